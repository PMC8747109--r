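#' Configuration of the stochastic colonization simulator
#'
#' The generative model emulates grid-intersect colonization data. Per
#' grid, a Poisson number of entry points (code 6) is placed uniformly;
#' from each entry a hyphal run (code 1) grows down its column, continuing
#' cell-to-cell with probability `extension_prob` and spreading to an
#' adjacent column with probability `lateral_prob` per new cell (lateral
#' cells start runs of their own). Each occupied non-entry cell then
#' differentiates independently: to an arbuscule (code 2) with probability
#' `p_arb`, otherwise to a vesicle (code 3) with probability `p_ves`,
#' otherwise it stays hyphal. Entry points keep their own code and are
#' excluded from the arbuscule-conversion denominator, since arbuscules
#' form on intraradical hyphae.
#'
#' Between-segment heterogeneity is modelled by a gamma-distributed
#' multiplier on `entry_rate` (shape and rate both `segment_dispersion`,
#' so the mean rate is preserved); smaller values give more contrast
#' between weakly and strongly colonized segments, which is what lets the
#' simulated frequencies span all five classes.
#'
#' The default design reproduces a 4-replication study with 15 one-cm
#' segments per replication and 15 microscopic fields per segment:
#' 4 x 15 x 15 = 900 grids over 60 segments. Default colonization
#' parameters are those of the `festuca_like` preset (see
#' [colonization_preset()]); `p_arb` defaults to 0.2, i.e. one in five
#' intraradical hyphal cells differentiates into an arbuscule.
#'
#' @param replications Number of replications.
#' @param segments_per_replication Segments per replication.
#' @param fields_per_segment Microscopic fields per segment.
#' @param entry_rate Expected entry points per grid (Poisson mean).
#' @param extension_prob Probability a hyphal run continues to the next
#'   cell down its column.
#' @param lateral_prob Probability a new hyphal cell also seeds the
#'   adjacent column.
#' @param p_arb Probability an occupied non-entry cell differentiates to
#'   an arbuscule.
#' @param p_ves Probability of vesicle differentiation (applied after the
#'   arbuscule draw fails).
#' @param segment_dispersion Gamma shape of the per-segment entry-rate
#'   multiplier; `Inf` disables heterogeneity.
#' @param seed Integer RNG seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(replications = 4,
                              segments_per_replication = 15,
                              fields_per_segment = 15,
                              entry_rate = 4,
                              extension_prob = 0.8,
                              lateral_prob = 0.35,
                              p_arb = 0.2,
                              p_ves = 0.08,
                              segment_dispersion = 1.2,
                              seed = 42) {
  probs <- c(extension_prob = extension_prob, lateral_prob = lateral_prob,
             p_arb = p_arb, p_ves = p_ves)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  if (entry_rate < 0) stop("entry_rate must be >= 0")
  stopifnot(replications >= 1, segments_per_replication >= 1,
            fields_per_segment >= 1, segment_dispersion > 0)
  structure(list(replications = as.integer(replications),
                 segments_per_replication =
                   as.integer(segments_per_replication),
                 fields_per_segment = as.integer(fields_per_segment),
                 entry_rate = entry_rate,
                 extension_prob = extension_prob,
                 lateral_prob = lateral_prob,
                 p_arb = p_arb, p_ves = p_ves,
                 segment_dispersion = segment_dispersion,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# simulate one 10 x 10 grid; RNG state is the caller's
.simulate_grid <- function(entry_rate, extension_prob, lateral_prob,
                           p_arb, p_ves) {
  m <- matrix(0L, 10, 10)
  n_entry <- stats::rpois(1, entry_rate)
  if (n_entry == 0) return(m)
  pos <- sample.int(100, min(n_entry, 100))
  m[pos] <- 6L
  stack <- lapply(pos, function(p)
    c(row = (p - 1) %% 10 + 1, col = (p - 1) %/% 10 + 1))
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    r <- cur[["row"]]; cc <- cur[["col"]]
    while (r < 10 && stats::runif(1) < extension_prob) {
      r <- r + 1
      if (m[r, cc] == 0L) m[r, cc] <- 1L
      if (stats::runif(1) < lateral_prob) {
        side <- if (stats::runif(1) < 0.5) -1L else 1L
        nc <- cc + side
        if (nc >= 1 && nc <= 10 && m[r, nc] == 0L) {
          m[r, nc] <- 1L
          stack[[length(stack) + 1]] <- c(row = r, col = nc)
        }
      }
    }
  }
  hyph <- which(m == 1L)
  if (length(hyph)) {
    u1 <- stats::runif(length(hyph))
    u2 <- stats::runif(length(hyph))
    m[hyph[u1 < p_arb]] <- 2L
    m[hyph[u1 >= p_arb & u2 < p_ves]] <- 3L
  }
  m
}

#' Simulate a dataset of coded colonization grids
#'
#' Deterministic given `config` (including its seed): the same
#' configuration always produces cell-identical grids.
#'
#' @param config A [simulation_config()].
#' @return List of [colonization_grid()] objects, one per
#'   replication x segment x field, in design order.
#' @export
#' @examples
#' grids <- simulate_dataset(simulation_config(replications = 1,
#'   segments_per_replication = 2, fields_per_segment = 3, seed = 1))
#' length(grids)  # 6
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, {
    grids <- vector("list",
                    config$replications * config$segments_per_replication *
                      config$fields_per_segment)
    idx <- 1L
    for (rep_i in seq_len(config$replications)) {
      for (seg in seq_len(config$segments_per_replication)) {
        rate <- if (is.finite(config$segment_dispersion))
          config$entry_rate * stats::rgamma(1,
                                            shape = config$segment_dispersion,
                                            rate = config$segment_dispersion)
        else config$entry_rate
        for (fld in seq_len(config$fields_per_segment)) {
          cells <- .simulate_grid(rate, config$extension_prob,
                                  config$lateral_prob, config$p_arb,
                                  config$p_ves)
          grids[[idx]] <- colonization_grid(rep_i, seg, fld, cells)
          idx <- idx + 1L
        }
      }
    }
    grids
  })
}

#' Named simulator presets
#'
#' * `sparse`: weak colonization (entry rate 0.5, extension 0.3) — most
#'   grids nearly empty.
#' * `festuca_like`: calibrated so that, over the default 900-grid design,
#'   roughly two thirds of observations have intensity at or below 20
#'   percent, arbuscule abundance rarely exceeds 5 percent, and the
#'   frequencies span all five classes.
#' * `saturated`: extreme colonization pressure; every column of every
#'   grid is reached, so frequency is 100 throughout.
#'
#' @param name One of `"sparse"`, `"festuca_like"`, `"saturated"`.
#' @param seed Integer RNG seed stored in the returned config.
#' @return A [simulation_config()].
#' @export
colonization_preset <- function(name = c("sparse", "festuca_like",
                                         "saturated"),
                                seed = 42) {
  name <- match.arg(name)
  switch(name,
    sparse = simulation_config(entry_rate = 0.5, extension_prob = 0.3,
                               lateral_prob = 0.1, p_ves = 0.05,
                               seed = seed),
    festuca_like = simulation_config(seed = seed),
    saturated = simulation_config(entry_rate = 200, extension_prob = 1,
                                  lateral_prob = 1, p_arb = 0, p_ves = 0,
                                  segment_dispersion = Inf, seed = seed))
}
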