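make_records <- function(freqs, seed = 1) {
  withr::with_seed(seed, {
    n <- length(freqs)
    intensity <- pmin(freqs, freqs * runif(n, 0.25, 0.45))
    arb <- intensity * runif(n, 0.1, 0.3)
    tibble::tibble(
      frequency = freqs, intensity = intensity, arbuscules = arb,
      vesicles = intensity * 0.05,
      colonization_degree = freqs * intensity / 100,
      non_mycorrhizal = 100 - intensity,
      m_nonm_ratio = intensity / (100 - intensity),
      freq_class = assign_class(freqs))
  })
}

test_that("histogram counts are conserved and class bins are fixed", {
  recs <- tibble::tibble(frequency = rep(50, 100))
  h <- col_histogram(recs, "frequency", "best_fitted")
  expect_equal(sum(h$counts), 100)
  expect_equal(sum(h$counts > 0), 1)

  recs2 <- tibble::tibble(frequency = 1:100)
  h2 <- col_histogram(recs2, "frequency", "class_restricted")
  expect_equal(h2$breaks, c(0, 20, 40, 60, 80, 100))
  expect_equal(h2$counts, rep(20, 5))

  withr::with_seed(3, recs3 <- tibble::tibble(frequency = runif(900, 0, 100)))
  h3 <- col_histogram(recs3, "frequency", "class_restricted")
  expect_length(h3$counts, 5)
  expect_equal(sum(h3$counts), 900)
  hb <- col_histogram(recs3, "frequency", "best_fitted")
  expect_equal(sum(hb$counts), 900)

  expect_error(col_histogram(recs3, "no_such_parameter"), "unknown")
})

test_that("ANOVA with identical groups collapses to one letter", {
  recs <- tibble::tibble(value = rep(5, 10),
                         grp = rep(c("g1", "g2"), each = 5))
  a <- anova_lsd(recs, "value", group = "grp")
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
  expect_true(all(a$table$letter == "a"))
})

test_that("clearly separated groups get distinct letters and match the F oracle", {
  withr::with_seed(4, {
    recs <- tibble::tibble(
      value = c(rnorm(10, 0, 0.01), rnorm(10, 10, 0.01)),
      grp = rep(c("low", "high"), each = 10))
  })
  a <- anova_lsd(recs, "value", group = "grp")
  expect_lt(a$p, 0.001)
  expect_equal(a$F, oracle_anova_f(recs$value, recs$grp), tolerance = 1e-8)
  expect_identical(a$table$letter[a$table$group == "high"], "a")
  expect_identical(a$table$letter[a$table$group == "low"], "b")
})

test_that("letters run a..e down strictly ordered class means", {
  withr::with_seed(8, {
    recs <- tibble::tibble(
      value = c(rnorm(20, 90, 1), rnorm(20, 70, 1), rnorm(20, 50, 1),
                rnorm(20, 30, 1), rnorm(20, 6, 1)),
      grp = rep(paste0("M", 5:1), each = 20))
  })
  a <- anova_lsd(recs, "value", group = "grp")
  tab <- a$table[order(-a$table$mean), ]
  expect_identical(tab$letter, letters[1:5])
})

test_that("LSD letters agree with exhaustive pairwise t-tests on 20-record fixtures", {
  withr::with_seed(12, {
    for (i in 1:20) {
      k <- sample(3:5, 1)
      means <- sample(seq(0, 40, by = 2), k)
      n_per <- 20 %/% k
      grp <- rep(paste0("g", seq_len(k)), each = n_per)
      val <- rnorm(length(grp), means[as.integer(factor(grp))], 3)
      recs <- tibble::tibble(value = val, grp = grp)
      a <- anova_lsd(recs, "value", group = "grp")
      if (a$p >= a$alpha) {
        expect_true(all(a$table$letter == "a"))
        next
      }
      pairs <- oracle_lsd_pairs(val, grp, alpha = a$alpha)
      tab <- a$table
      for (x in seq_len(nrow(tab))) for (y in seq_len(nrow(tab))) {
        if (y <= x) next
        shares <- any(strsplit(tab$letter[x], "")[[1]] %in%
                        strsplit(tab$letter[y], "")[[1]])
        differs <- pairs[tab$group[x], tab$group[y]]
        expect_identical(!shares, differs)
      }
    }
  })
})

test_that("ANOVA guards degenerate groupings", {
  recs <- tibble::tibble(value = c(1, 2, 3), grp = c("a", "a", "b"))
  expect_warning(expect_error(anova_lsd(recs, "value", group = "grp"),
                              "at least 2 groups"),
                 "fewer than 2")
})

test_that("regression matches the normal-equation oracle", {
  recs <- tibble::tibble(x = 1:10, y = 1:10)
  # exact line: lm warns that the perfect-fit summary is unreliable
  r <- suppressWarnings(fit_regression(recs, "x", "y"))
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$predict_at(50), 50)

  recs2 <- tibble::tibble(x = c(1, 3, 4, 7, 11), y = c(2, 3, 9, 7, 12))
  r2 <- fit_regression(recs2, "x", "y")
  o <- oracle_ols(recs2$x, recs2$y)
  expect_equal(r2$slope, unname(o["slope"]), tolerance = 1e-8)
  expect_equal(r2$intercept, unname(o["intercept"]), tolerance = 1e-8)
  # residuals orthogonal to the predictor
  res <- stats::residuals(r2$model)
  expect_lt(abs(sum(res * recs2$x)), 1e-6 * nrow(recs2))

  expect_error(fit_regression(tibble::tibble(x = rep(2, 5), y = 1:5),
                              "x", "y"), "zero variance")
})

test_that("regression recovers a planted arbuscule conversion slope", {
  withr::with_seed(99, {
    intensity <- runif(500, 0, 60)
    recs <- tibble::tibble(intensity = intensity,
                           arbuscules = 0.16 * intensity + rnorm(500, 0, 1))
  })
  r <- fit_regression(recs, "intensity", "arbuscules")
  expect_equal(r$slope, 0.16, tolerance = 0.02 / 0.16)
  expect_true(abs(r$slope - 0.16) < 0.02)
})

test_that("PCA axis variances behave and match a hand-computed eigendecomposition", {
  # two perfectly correlated variables: one axis carries everything
  recs <- tibble::tibble(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  p <- pca_indices(recs, variables = c("a", "b"))
  expect_equal(p$var_pct[1], 100, tolerance = 1e-8)

  # 3-point toy matrix vs. eigen() of the correlation matrix
  m <- tibble::tibble(a = c(1, 2, 4), b = c(1, 3, 2), c = c(5, 1, 2))
  p3 <- pca_indices(m, variables = c("a", "b", "c"))
  ev <- eigen(stats::cor(as.matrix(m)))$values
  expect_equal(100 * ev / sum(ev), p3$var_pct, tolerance = 1e-8)
  expect_true(all(diff(p3$var_pct) <= 1e-12))
  expect_equal(sum(p3$var_pct), 100, tolerance = 1e-8)

  recs_c <- tibble::tibble(a = 1:5, b = (1:5)^2, d = rep(3, 5))
  expect_warning(pca_indices(recs_c, variables = c("a", "b", "d")),
                 "constant")
})

test_that("intensity and non-mycorrhizal vectors oppose each other in PCA", {
  grids <- simulate_dataset(simulation_config(seed = 6, replications = 1))
  recs <- compute_indices_table(grids)
  p <- pca_indices(recs)
  li <- p$loadings["intensity", 1:2]
  ln <- p$loadings["non_mycorrhizal", 1:2]
  expect_lt(sum(li * ln), 0)           # opposite half-planes
  expect_equal(unname(li), -unname(ln), tolerance = 1e-8)  # exact complement
})

test_that("NMDS embeds 4 equidistant points at ~zero stress and preserves ranks", {
  recs <- tibble::tibble(a = c(10, 0, 0, 5), b = c(0, 10, 0, 5),
                         c = c(0, 0, 10, 5), d = c(5, 5, 5, 0))
  # 20-record fixture: configuration distances rank-correlate with input
  withr::with_seed(31, {
    recs20 <- tibble::tibble(a = runif(20, 0, 50), b = runif(20, 0, 30),
                             c = runif(20, 0, 10))
  })
  n <- nmds_indices(recs20, variables = c("a", "b", "c"), seed = 7)
  expect_gte(n$stress, 0)
  d_in <- vegan::vegdist(as.matrix(recs20), method = "bray")
  d_out <- stats::dist(n$scores)
  expect_gt(stats::cor(as.vector(d_in), as.vector(d_out),
                       method = "spearman"), 0.95)

  four <- tibble::tibble(a = c(1, 0, 0, 0), b = c(0, 1, 0, 0),
                         c = c(0, 0, 1, 0), d = c(0, 0, 0, 1))
  n4 <- suppressWarnings(
    nmds_indices(four, variables = c("a", "b", "c", "d"), seed = 1,
                 try = 5, trymax = 5))
  expect_lt(n4$stress, 0.01)

  same <- tibble::tibble(a = rep(1, 5), b = rep(1, 5))
  expect_error(
    suppressWarnings(nmds_indices(same, variables = c("a", "b"))),
    "identical|constant")
})

test_that("NMDS and PCA ordinations agree on simulated colonization data", {
  grids <- simulate_dataset(simulation_config(seed = 14, replications = 1,
                                              segments_per_replication = 8))
  recs <- compute_indices_table(grids)
  p <- pca_indices(recs)
  n <- nmds_indices(recs, seed = 14, try = 5, trymax = 10)
  pro <- vegan::protest(p$scores[, 1:2], n$scores, permutations = 199)
  expect_gt(pro$t0, 0.8)  # Procrustes correlation
})

test_that("clustering recovers planted structure and reports centroids", {
  # k = 1: everything in one cluster, centroid = global mean
  recs <- make_records(c(5, 15, 35, 55, 75, 95), seed = 2)
  c1 <- cluster_strategies(recs, k = 1)
  expect_identical(unique(c1$assignment$cluster), "C1")
  expect_equal(c1$centroids$frequency, mean(recs$frequency))
  expect_equal(c1$centroids$share_pct, 100)

  # two well-separated blobs are recovered perfectly
  withr::with_seed(17, {
    blob <- function(f0) make_records(f0 + runif(15, 0, 3), seed = f0)
    recs2 <- dplyr::bind_rows(blob(5), blob(85))
    truth <- rep(c("C1", "C2"), each = 15)
  })
  c2 <- cluster_strategies(recs2, k = 2)
  expect_identical(c2$assignment$cluster, truth)
  expect_equal(sum(c2$centroids$share_pct), 100)
  # centroid complement identity
  expect_equal(c2$centroids$non_mycorrhizal,
               100 - c2$centroids$intensity)

  # permutation invariance (up to relabelling)
  withr::with_seed(23, perm <- sample(nrow(recs2)))
  c3 <- cluster_strategies(recs2[perm, ], k = 2)
  lab2 <- c2$assignment$cluster[perm]
  agree <- table(lab2, c3$assignment$cluster)
  expect_true(all(rowSums(agree > 0) == 1), info = "partition preserved")

  expect_error(cluster_strategies(recs, k = 10), "exceeds")
})

test_that("strategy reports pick the member nearest each centroid", {
  grids <- simulate_dataset(simulation_config(seed = 5, replications = 1,
                                              segments_per_replication = 10,
                                              fields_per_segment = 5))
  recs <- compute_indices_table(grids)
  seg_means <- dplyr::summarise(
    dplyr::group_by(recs, replication, segment),
    dplyr::across(dplyr::all_of(c("frequency", "intensity", "arbuscules",
                                  "vesicles", "colonization_degree",
                                  "non_mycorrhizal", "m_nonm_ratio")),
                  mean),
    .groups = "drop")
  cl <- cluster_strategies(seg_means, k = 3)
  rep3 <- strategy_report(cl, grids)
  expect_length(rep3$clusters, 3)
  # exhaustive-search oracle for the representative member
  xs <- scale(as.matrix(cl$assignment[, cl$variables]),
              center = cl$center, scale = cl$scale)
  for (entry in rep3$clusters) {
    members <- which(cl$assignment$cluster == entry$cluster)
    cent <- unlist(cl$centroids[cl$centroids$cluster == entry$cluster,
                                cl$variables])
    cent_s <- (cent - cl$center) / cl$scale
    d <- apply(xs[members, , drop = FALSE], 1,
               function(r) sum((r - cent_s)^2))
    best <- cl$assignment$segment[members[which.min(d)]]
    expect_identical(entry$representative$segment, best)
    expect_s3_class(entry$map, "colonization_map")
  }

  # single cluster: one map plus one centroid row
  cl1 <- cluster_strategies(seg_means, k = 1)
  rep1 <- strategy_report(cl1, grids)
  expect_length(rep1$clusters, 1)
  expect_identical(nrow(rep1$centroids), 1L)
})
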