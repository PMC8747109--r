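---
title: "Quantifying mycorrhizal colonization patterns from coded grids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mycorrhizal colonization patterns from coded grids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycopattern)
```

## The measurement model

Arbuscular mycorrhizal (AM) colonization of cleared and stained roots is
scored under the microscope by overlaying each microscopic field with a
10 × 10 grid and coding every cell for the fungal structure it contains:
0 empty, 1 hyphae, 2 arbuscule, 3 vesicle, 4 spore, 5 auxiliary cell,
6 entry point. A cell holds exactly one code, so the six structures
partition the colonized area of the field. Rows of the grid are the
transverse position in the root; columns run along the root axis, so a
column is "one position along the root". The package assumes a standard
sampling design of 4 replications × 15 one-cm segments × 15 fields per
segment = 900 coded grids over 60 segments, but none of the functions
depend on those counts.

From each grid, `compute_indices()` derives the seven standard indices:

* **Frequency (F, %)** — 10 × the number of columns containing any
  structure. Frequency measures the root's *primary permissiveness*: how
  much of the root length the symbiont has reached at all. Because a
  column either is or is not colonized, F moves in steps of 10.
* **Intensity (I, %)** — the number of occupied cells (out of 100).
  Intensity is the *secondary permissiveness*: how densely a reached
  area is actually colonized. Since an occupied column contains at most
  10 occupied cells, `I <= F` for every grid (a pigeonhole argument the
  test suite checks on random grids).
* **Arbuscule and vesicle abundance (%)** — counts of codes 2 and 3, as
  a share of *all* 100 cells. The absolute convention (rather than a
  share of colonized cells) is what makes the arbuscule-on-intensity
  regression slope directly comparable with a per-hypha conversion
  probability.
* **Colonization degree (%)** — `F × I / 100`, a volumetric synthesis of
  extent and density.
* **Non-mycorrhizal area (%)** — exactly `100 − I`.
* **Mycorrhizal/non-mycorrhizal report** — `I / (100 − I)`. A fully
  colonized field (I = 100) would divide by zero; it is reported as the
  sentinel 99 with a warning, since "fully colonized" is a biological
  statement, not a numerical accident. The sentinel only matters for
  saturated synthetic data; field observations of grasses sit far from
  I = 100.

Frequency is also the analysis's coding variable: `assign_class()` bins
it into five 20-wide classes M1 (low, [0, 20]) through M5 (high,
(80, 100]). The class bounds are half-open on the left so that the five
classes partition [0, 100] even for non-integer frequencies; an exact
20 falls in M1. Report tables round to 2 decimals; all internal
computation is at full precision.

## Statistical stages

**Histograms.** Each index is binned two ways: a `best_fitted` solution
using the standard automatic rule (Sturges bin count with pretty break
points — for ~900 percentage values this gives 10-wide bins), and a
`class_restricted` solution that forces the five 20-wide class bins, so
that every parameter can be read against the frequency-class framework.

**Class dynamics.** `anova_lsd()` runs a one-way ANOVA of an index over
the classes, followed by Fisher's least-significant-difference pairwise
comparisons summarized as a compact letter display (insert-and-absorb
algorithm, letters assigned in descending mean order so the largest
mean is always "a"). The LSD stage is *protected*: pairwise tests are
only made when the omnibus F is significant at `alpha`. Unprotected
pairwise testing at `alpha = 0.05` over five groups would split letters
in far more than 5% of null datasets; the protected variant keeps that
rate at the nominal level, which the test suite verifies over 200 null
simulations. ANOVA is run on per-observation records (n = 900 under the
default design), which is what produces the very large F statistics
typical of this design. A response with literally zero variance is
reported as F = 0, p = 1 (the least-squares F on a perfect fit is
numerically meaningless).

**Regressions.** `fit_regression()` is ordinary least squares; the
pipeline fits the five canonical pairs — frequency→intensity,
frequency→arbuscules, intensity→arbuscules, degree→arbuscules and
degree→ratio. The intercept is the base level of the response and the
slope its gain per unit of predictor; the intensity→arbuscules slope in
particular estimates the fraction of hyphal cells converted to
arbuscules.

**Ordination.** `pca_indices()` uses correlation-matrix PCA (centred,
unit-variance-scaled): the indices mix percent scales with the
dimensionless ratio, so covariance PCA would be dominated by whichever
index has the largest variance. Because the non-mycorrhizal area is the
exact complement of intensity, their loadings are exactly opposite —
the antagonistic intensity/non-colonized gradient is a structural
feature of the index system, not a biological finding.
`nmds_indices()` runs two-dimensional NMDS on Bray–Curtis
dissimilarities of the raw (non-negative) index values with 20 seeded
random restarts. The dissimilarity is computed explicitly and passed to
the engine as a distance object: community-ecology conveniences
(square-root/Wisconsin autotransforms, step-across correction) are
deliberate *non*-choices here, since indices are not species counts. On
well-structured colonization data, PCA and NMDS give closely agreeing
configurations (Procrustes correlation above 0.8 in the test suite).

**Strategy clustering.** `cluster_strategies()` standardizes
segment-level mean records, builds a Euclidean-distance Ward
(`ward.D2`) dendrogram and cuts it into k = 9 groups. Ward linkage is
chosen because it produces compact clusters whose centroids (raw-scale
member means, the "middle point" of the cluster) are meaningful
summaries; the cut at nine follows the strategy-typing convention this
analysis implements. Clusters are relabelled C1..Ck in input order of
their first member, which makes the partition invariant (up to labels)
under permutations of the input. `strategy_report()` then picks, per
cluster, the member nearest the centroid in the standardized index
space — and within that segment the field whose own indices are nearest
the centroid — and renders its colonization map, giving one
representative 10 × 10 colour map per strategy: hyphae blue, arbuscules
red, vesicles green, entry points purple, non-colonized cells white
(spores orange and auxiliary cells yellow are package conventions; they
are rare enough that published maps do not show them).

## The synthetic-data generator

Real scored roots are rarely redistributable, so `simulate_dataset()`
generates coded grids with the statistical structure the analysis
expects. Per grid, a Poisson(`entry_rate`) number of entry points is
placed uniformly; each seeds a hyphal run that grows down its column
with continuation probability `extension_prob`, and every new hyphal
cell spreads into an adjacent column with probability `lateral_prob`
(lateral cells start runs of their own). Each occupied non-entry cell
then differentiates independently: arbuscule with probability `p_arb`
(default 0.2 — about one in five intraradical hyphal cells forms an
arbuscule), otherwise vesicle with probability `p_ves`. Entry points
keep their own code and are excluded from the conversion denominator,
since arbuscules form on hyphae.

Separating entry placement from extension makes frequency (driven by
how many columns are reached) and intensity (driven by how far runs
extend) two distinct knobs — colonization with constant root
penetration but fluctuating success. One parameter goes beyond that
list: `segment_dispersion`, a gamma-distributed multiplier on the entry
rate drawn once per segment (shape = rate = `segment_dispersion`, mean
1). Without between-segment heterogeneity a homogeneous simulator
concentrates all 900 frequencies in one or two classes; field data span
the whole 0–100 range and group into distinct per-segment strategies,
and the gamma mixing is the simplest mechanism that reproduces both.

The `festuca_like` preset (also the `simulation_config()` default:
`entry_rate = 4`, `extension_prob = 0.8`, `lateral_prob = 0.35`,
`p_ves = 0.08`, `segment_dispersion = 1.2`) was calibrated once, by a
coarse grid search, against the distributional facts a grass-root
dataset of this design shows: about two thirds of observations with
intensity ≤ 20% (the package tests accept 0.56–0.76), arbuscule
abundance only rarely above 5%, frequencies populating all five
classes, and a fitted intensity→arbuscule slope consistent with the
0.2 conversion probability (the recovered slope is slightly below 0.2
because entry points count toward intensity but never convert). Across
simulation seeds 1–10 the preset holds all of these simultaneously.

What the simulator does *not* emulate: real spatial morphology of
hyphal networks (no arc-shaped runs, no inter-cell avoidance), spores
and auxiliary cells (never generated; they are rare in root cortex
preparations), within-root autocorrelation beyond simple lateral
spread (`lateral_prob` is unconstrained by any published statistic and
is documented as a free parameter), and any host–fungus feedback.
Passing tests on simulated data therefore validate the *computational
pipeline* — index arithmetic, class statistics, ordination and
clustering behaviour — not biological claims about any particular
grassland.

## Numerical and design choices

* Sparse grid tables: only non-empty cells are written; an all-empty
  grid is represented by one explicit code-0 row so round trips are
  exact identities.
* Duplicate cell entries are rejected (with both line numbers) rather
  than resolved silently; an incomplete design (missing field) is a
  warning, not an error, because the statistics pool whatever was
  observed.
* Ratio sentinel 99 at I = 100, with a warning, as discussed above.
* NMDS restarts are seeded (`seed` argument, default 42), making the
  whole pipeline byte-reproducible for a fixed configuration — the
  test suite compares md5 checksums of two complete report bundles.
* Degenerate inputs degrade softly in the pipeline: constant predictors
  skip their regression, all-constant indices skip ordination, and
  empty frequency classes are dropped with a warning; each skip is
  recorded in the run log.
* Problem sizes in the tests are chosen to exercise the full default
  design where the property under test needs it (900-grid simulations,
  10 seeds for recovery checks) and small fixtures everywhere else.

## Limitations

The index reconstructions (frequency as column presence, intensity as
cell occupancy, degree as F·I/100) are anchored to the exact
complement/product identities that published class and cluster tables
satisfy, but the upstream scoring tool is not open source, so
per-observation agreement with it cannot be verified directly. The
package starts from coded grids: structure identification from
micrographs is upstream, manual work. Nine clusters is a convention,
not an optimum; `k_clusters` is exposed for a reason. And all
distributional defaults describe lightly colonized perennial grass
roots — other hosts (heavily colonized crops, for instance) will need
their own `simulation_config()`.
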