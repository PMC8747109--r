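#' Histogram of one colonization parameter
#'
#' Two binning solutions are supported. `best_fitted` uses the standard
#' automatic rule (Sturges bin count with pretty break points, as in base
#' histograms), which for ~900 percentage observations on 0-100 gives
#' 10-percent-wide bins. `class_restricted` forces the five 20-wide
#' frequency-class bins \[0,20\], (20,40\], (40,60\], (60,80\], (80,100\],
#' so every parameter is read on the frequency-class scale.
#'
#' @param records Tibble of colonization records.
#' @param parameter Name of the index column to bin.
#' @param solution `"best_fitted"` or `"class_restricted"`.
#' @return List of class `colonization_histogram`: `parameter`, `solution`,
#'   `breaks`, `counts` (`sum(counts) == nrow(records)`), `mids`.
#' @export
col_histogram <- function(records,
                          parameter,
                          solution = c("best_fitted", "class_restricted")) {
  solution <- match.arg(solution)
  if (!parameter %in% names(records))
    stop("unknown parameter: ", parameter)
  x <- records[[parameter]]
  stopifnot(length(x) >= 1)
  if (solution == "class_restricted") {
    h <- graphics::hist(x, breaks = c(0, 20, 40, 60, 80, 100),
                        include.lowest = TRUE, right = TRUE, plot = FALSE)
  } else {
    h <- graphics::hist(x, breaks = "Sturges", plot = FALSE)
  }
  structure(list(parameter = parameter, solution = solution,
                 breaks = h$breaks, counts = h$counts, mids = h$mids),
            class = "colonization_histogram")
}

# pooled-variance pairwise t test p-value (Fisher's LSD)
.lsd_p <- function(mi, mj, ni, nj, mse, df) {
  se <- sqrt(mse * (1 / ni + 1 / nj))
  if (se == 0) return(if (mi == mj) 1 else 0)
  2 * stats::pt(-abs(mi - mj) / se, df)
}

# insert-and-absorb compact letter display.
# `diff` is a logical matrix over groups ordered by descending mean;
# TRUE means the pair differs significantly.
.cld_insert_absorb <- function(diff) {
  g <- nrow(diff)
  cols <- list(rep(TRUE, g))
  for (i in seq_len(g)) for (j in seq_len(g)) {
    if (j <= i || !diff[i, j]) next
    newcols <- list()
    for (col in cols) {
      if (col[i] && col[j]) {
        c1 <- col; c1[i] <- FALSE
        c2 <- col; c2[j] <- FALSE
        newcols <- c(newcols, list(c1, c2))
      } else {
        newcols <- c(newcols, list(col))
      }
    }
    # absorb columns whose membership is contained in another column
    keep <- rep(TRUE, length(newcols))
    for (a in seq_along(newcols)) for (b in seq_along(newcols)) {
      if (a == b || !keep[a] || !keep[b]) next
      sub <- all(!newcols[[a]] | newcols[[b]])
      if (sub && (!all(!newcols[[b]] | newcols[[a]]) || a > b))
        keep[a] <- FALSE
    }
    cols <- newcols[keep]
  }
  first <- vapply(cols, function(col) which(col)[1], 1L)
  cols <- cols[order(first)]
  letters_out <- character(g)
  for (ci in seq_along(cols))
    letters_out[cols[[ci]]] <- paste0(letters_out[cols[[ci]]],
                                      letters[ci])
  letters_out
}

#' One-way ANOVA with protected-LSD letter display
#'
#' Tests whether the mean of a colonization parameter differs between
#' groups (by default the five frequency classes) with a one-way ANOVA,
#' then summarizes pairwise differences with Fisher's least significant
#' difference test and a compact letter display. The LSD stage is
#' *protected*: pairwise comparisons are only made when the omnibus F test
#' is significant at `alpha`, which keeps the null rate of spurious letter
#' splits at the nominal level. Letters are assigned in order of
#' descending group mean, so the highest mean is always lettered `a`.
#'
#' @param records Tibble of colonization records.
#' @param parameter Index column to analyse.
#' @param group Grouping column (default `"freq_class"`).
#' @param alpha Significance level (default 0.05).
#' @return List of class `colonization_anova`: `parameter`, `F`, `p`,
#'   `alpha`, `df`, and `table` (group, mean, se, n, letter).
#' @export
anova_lsd <- function(records, parameter, group = "freq_class",
                      alpha = 0.05) {
  stopifnot(parameter %in% names(records), group %in% names(records),
            alpha > 0, alpha < 1)
  d <- data.frame(value = records[[parameter]],
                  group = as.character(records[[group]]))
  n_by <- table(d$group)
  small <- names(n_by)[n_by < 2]
  if (length(small)) {
    warning("group(s) with fewer than 2 records excluded: ",
            paste(small, collapse = ", "))
    d <- d[!d$group %in% small, ]
  }
  groups <- sort(unique(d$group))
  if (length(groups) < 2)
    stop("need at least 2 groups with >= 2 records each")
  if (stats::var(d$value) == 0) {
    # perfect fit: no variation anywhere, nothing to separate
    f_stat <- 0; p_val <- 1; mse <- 0
    df_err <- nrow(d) - length(groups)
  } else {
    fit <- stats::aov(value ~ group, data = d)
    an <- stats::anova(fit)
    f_stat <- an[["F value"]][1]
    p_val <- an[["Pr(>F)"]][1]
    mse <- an[["Mean Sq"]][2]
    df_err <- an[["Df"]][2]
  }
  stats_tbl <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(d), .data$group),
    mean = mean(.data$value),
    se = stats::sd(.data$value) / sqrt(dplyr::n()),
    n = dplyr::n(), .groups = "drop")
  ord <- order(-stats_tbl$mean)
  m <- stats_tbl$mean[ord]; nn <- stats_tbl$n[ord]
  g <- length(m)
  diff <- matrix(FALSE, g, g)
  if (is.finite(p_val) && p_val < alpha) {
    for (i in seq_len(g)) for (j in seq_len(g)) {
      if (j <= i) next
      diff[i, j] <- .lsd_p(m[i], m[j], nn[i], nn[j], mse, df_err) < alpha
    }
  }
  let <- .cld_insert_absorb(diff)
  stats_tbl$letter <- let[match(seq_len(nrow(stats_tbl)), ord)]
  structure(list(parameter = parameter, F = f_stat, p = p_val,
                 alpha = alpha, df = c(length(groups) - 1, df_err),
                 table = stats_tbl),
            class = "colonization_anova")
}

#' @export
print.colonization_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA of %s: F(%d, %d) = %.2f, p = %.3g\n",
              x$parameter, x$df[1], x$df[2], x$F, x$p))
  print(x$table)
  invisible(x)
}

#' Ordinary least-squares regression between two colonization parameters
#'
#' Fits the straight-line dependence of one index on another (e.g.
#' intensity on frequency, arbuscules on intensity); the intercept is the
#' base level of the response and the slope its gain per unit of the
#' predictor.
#'
#' @param records Tibble of colonization records (>= 3 rows).
#' @param predictor,response Index column names.
#' @return List of class `colonization_regression`: `predictor`,
#'   `response`, `intercept`, `slope`, `sigma` (residual standard error),
#'   `r_squared`, `model` (the `lm` fit) and `predict_at(x)`.
#' @export
fit_regression <- function(records, predictor, response) {
  stopifnot(predictor %in% names(records), response %in% names(records),
            nrow(records) >= 3)
  x <- records[[predictor]]; y <- records[[response]]
  if (stats::var(x) == 0) stop("predictor has zero variance")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  structure(list(predictor = predictor, response = response,
                 intercept = unname(co[1]), slope = unname(co[2]),
                 sigma = summary(fit)$sigma,
                 r_squared = summary(fit)$r.squared,
                 model = fit,
                 predict_at = function(newx)
                   unname(co[1] + co[2] * newx)),
            class = "colonization_regression")
}

# the five regression pairs examined by the pipeline
.regression_pairs <- function() {
  list(c("frequency", "intensity"),
       c("frequency", "arbuscules"),
       c("intensity", "arbuscules"),
       c("colonization_degree", "arbuscules"),
       c("colonization_degree", "m_nonm_ratio"))
}

.ordination_matrix <- function(records, variables) {
  stopifnot(all(variables %in% names(records)))
  x <- as.matrix(records[, variables])
  rownames(x) <- paste0("obs", seq_len(nrow(x)))
  constant <- apply(x, 2, function(v) stats::var(v) == 0)
  if (any(constant)) {
    warning("constant variable(s) dropped: ",
            paste(variables[constant], collapse = ", "))
    x <- x[, !constant, drop = FALSE]
  }
  if (ncol(x) < 2) stop("need at least 2 non-constant variables")
  x
}

#' Principal component analysis of colonization indices
#'
#' PCA on centred, unit-variance-scaled indices (the indices mix percent
#' scales with the dimensionless ratio, so correlation-matrix PCA is
#' used). Constant variables are dropped with a warning.
#'
#' @param records Tibble of colonization records (>= 3 rows).
#' @param variables Index columns to ordinate; defaults to all present.
#' @return List of class `colonization_ordination`: `method = "PCA"`,
#'   `scores` (observations x axes), `loadings`, `var_pct` (percent
#'   variance per axis).
#' @export
pca_indices <- function(records,
                        variables = intersect(.index_cols, names(records))) {
  stopifnot(nrow(records) >= 3)
  x <- .ordination_matrix(records, variables)
  fit <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  var_pct <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  structure(list(method = "PCA", scores = fit$x, loadings = fit$rotation,
                 var_pct = var_pct),
            class = "colonization_ordination")
}

#' Non-metric multidimensional scaling of colonization indices
#'
#' Two-dimensional NMDS (via [vegan::metaMDS]) on the raw non-negative
#' index values with Bray-Curtis dissimilarity, using seeded random
#' restarts for reproducibility.
#'
#' @inheritParams pca_indices
#' @param distance Dissimilarity index passed to [vegan::metaMDS].
#' @param seed Integer seed for the random restarts.
#' @param try,trymax Minimum and maximum numbers of random starts.
#' @return List of class `colonization_ordination`: `method = "NMDS"`,
#'   `scores` (2-axis site configuration), `variable_scores` (weighted
#'   average positions of the indices), `stress`, `distance`.
#' @export
nmds_indices <- function(records,
                         variables = intersect(.index_cols, names(records)),
                         distance = "bray", seed = 42,
                         try = 20, trymax = 20) {
  stopifnot(nrow(records) >= 4)
  x <- .ordination_matrix(records, variables)
  if (any(x < 0)) stop("Bray-Curtis NMDS needs non-negative data")
  if (all(stats::dist(x) == 0)) stop("all observations identical")
  # indices are not community counts, so the dissimilarity is computed
  # directly (no square-root/Wisconsin autotransform, no step-across)
  dis <- vegan::vegdist(x, method = distance)
  fit <- withr::with_seed(seed,
    vegan::metaMDS(dis, k = 2, try = try, trymax = trymax, trace = 0))
  sites <- vegan::scores(fit, display = "sites")
  structure(list(method = "NMDS",
                 scores = sites,
                 variable_scores = vegan::wascores(sites, x),
                 stress = fit$stress, distance = distance,
                 model = fit),
            class = "colonization_ordination")
}

#' Cut a dendrogram of colonization records into strategy clusters
#'
#' Hierarchical agglomerative clustering of (typically segment-level mean)
#' colonization records: indices are centred and scaled to unit variance,
#' distances computed (Euclidean by default), the tree built with Ward
#' linkage and cut into `k` groups. Clusters are relabelled C1..Ck in
#' input order of their first member. Centroids are the raw-scale member
#' means of each index.
#'
#' @param records Tibble of colonization records; any non-index columns
#'   are carried through as member identifiers.
#' @param k Number of clusters to cut (default 9).
#' @param linkage Agglomeration method for [stats::hclust]
#'   (default `"ward.D2"`).
#' @param distance Distance metric for [stats::dist].
#' @return List of class `strategy_clusters`: `assignment` (records plus
#'   `cluster`), `centroids` (cluster, per-index mean, `n`, `share_pct`;
#'   shares sum to 100), `tree`, `k`, `variables`, and the scaling used
#'   (`center`, `scale`).
#' @export
cluster_strategies <- function(records, k = 9, linkage = "ward.D2",
                               distance = "euclidean") {
  stopifnot(nrow(records) >= 1)
  if (k > nrow(records)) stop("k exceeds the number of records")
  variables <- intersect(.index_cols, names(records))
  stopifnot(length(variables) >= 2)
  x <- as.matrix(records[, variables])
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0] <- 1  # constant columns contribute nothing either way
  ctr <- colMeans(x)
  xs <- scale(x, center = ctr, scale = sds)
  if (k == 1) {
    raw <- rep(1L, nrow(records))
    tree <- if (nrow(records) >= 2)
      stats::hclust(stats::dist(xs, method = distance), method = linkage)
    else NULL
  } else {
    tree <- stats::hclust(stats::dist(xs, method = distance),
                          method = linkage)
    raw <- stats::cutree(tree, k = k)
  }
  relabel <- match(raw, unique(raw))  # C1 = cluster of the first record
  assignment <- records
  assignment$cluster <- paste0("C", relabel)
  cent <- dplyr::summarise(
    dplyr::group_by(assignment, .data$cluster),
    dplyr::across(dplyr::all_of(variables), mean),
    n = dplyr::n(), .groups = "drop")
  cent$share_pct <- 100 * cent$n / nrow(records)
  cent <- cent[order(as.integer(sub("^C", "", cent$cluster))), ]
  structure(list(assignment = assignment, centroids = cent, tree = tree,
                 k = as.integer(k), variables = variables,
                 center = ctr, scale = sds),
            class = "strategy_clusters")
}

#' @export
print.strategy_clusters <- function(x, ...) {
  cat(sprintf("<strategy_clusters> k = %d over %d records\n", x$k,
              nrow(x$assignment)))
  print(x$centroids)
  invisible(x)
}

# squared Euclidean distance of scaled rows to a scaled centroid
.dist_to_centroid <- function(rows_scaled, centroid_scaled) {
  rowSums(sweep(rows_scaled, 2, centroid_scaled)^2)
}

#' Build the colonization-strategy report
#'
#' For each strategy cluster, selects the member record closest (Euclidean
#' distance in the standardized index space used for clustering) to the
#' cluster centroid, renders the colonization map of the matching grid via
#' [render_map()], and returns it together with the centroid table and
#' data shares. If members are segment-level means, the representative
#' grid is the field of that segment whose own indices lie nearest the
#' centroid; a cluster with no matching grid gets a `NULL` map
#' placeholder.
#'
#' @param clusters A [cluster_strategies()] result.
#' @param grids List of [colonization_grid()] objects covering the
#'   clustered records.
#' @return List of class `strategy_report`: `centroids`, and `clusters`,
#'   a list with per-cluster `cluster`, `representative` (id columns of
#'   the chosen member), `map`.
#' @export
strategy_report <- function(clusters, grids) {
  stopifnot(inherits(clusters, "strategy_clusters"))
  asg <- clusters$assignment
  vars <- clusters$variables
  xs <- scale(as.matrix(asg[, vars]), center = clusters$center,
              scale = clusters$scale)
  grid_idx <- if (length(grids))
    compute_indices_table(grids)
  else NULL
  out <- lapply(clusters$centroids$cluster, function(cl) {
    members <- which(asg$cluster == cl)
    cent_raw <- unlist(
      clusters$centroids[clusters$centroids$cluster == cl, vars])
    cent_s <- (cent_raw - clusters$center[vars]) / clusters$scale[vars]
    best <- members[which.min(.dist_to_centroid(
      xs[members, , drop = FALSE], cent_s))]
    id_cols <- intersect(c("replication", "segment", "field"), names(asg))
    rep_id <- asg[best, id_cols, drop = FALSE]
    map <- NULL
    if (!is.null(grid_idx)) {
      cand <- rep(TRUE, nrow(grid_idx))
      for (cn in id_cols) cand <- cand & grid_idx[[cn]] == rep_id[[cn]]
      cand <- which(cand)
      if (length(cand)) {
        gvars <- intersect(vars, names(grid_idx))
        gs <- scale(as.matrix(grid_idx[cand, gvars, drop = FALSE]),
                    center = clusters$center[gvars],
                    scale = clusters$scale[gvars])
        pick <- cand[which.min(.dist_to_centroid(
          gs, cent_s[match(gvars, vars)]))]
        gpick <- grid_idx[pick, c("replication", "segment", "field")]
        for (g in grids) {
          if (g$replication == gpick$replication &&
              g$segment == gpick$segment && g$field == gpick$field) {
            map <- render_map(g)
            break
          }
        }
      }
    }
    list(cluster = cl, representative = rep_id, map = map)
  })
  structure(list(centroids = clusters$centroids, clusters = out),
            class = "strategy_report")
}
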