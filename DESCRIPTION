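Package: mycopattern
Title: Quantification of Arbuscular Mycorrhizal Colonization Patterns from
    Coded Microscopic-Field Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for grid-intersect scoring of arbuscular mycorrhizal
    colonization in cleared and stained roots. Each microscopic field is a
    10 x 10 grid of coded fungal structures (hyphae, arbuscules, vesicles,
    spores, auxiliary cells, entry points); the package computes the seven
    standard colonization indices (frequency, intensity, arbuscule and
    vesicle abundance, colonization degree, non-mycorrhizal area, and the
    mycorrhizal/non-mycorrhizal ratio), bins observations into five
    frequency classes, and analyses class dynamics with ANOVA plus
    protected-LSD letter displays, pairwise regressions, PCA and NMDS
    ordination, and dendrogram-cut colonization-strategy clustering with
    colour-coded colonization maps. A stochastic lattice simulator
    generates coded grids with realistic colonization statistics so the
    whole pipeline can be exercised and tested without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    tibble,
    dplyr,
    rlang,
    vegan,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    png,
    optparse
Config/testthat/edition: 3
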