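#' Configuration of the full analysis pipeline
#'
#' @param input Path to a grid-table CSV, or `NULL` to simulate.
#' @param preset Simulator preset name used when `input` is `NULL`
#'   (see [colonization_preset()]).
#' @param out Output directory (created if needed).
#' @param alpha ANOVA/LSD significance level, in (0, 1).
#' @param k_clusters Number of strategy clusters to cut (>= 1).
#' @param seed Integer seed controlling simulation and NMDS restarts.
#' @param histogram Which histogram solutions to compute:
#'   `"both"`, `"best_fitted"` or `"class_restricted"`.
#' @param rounding Decimal places used in report CSVs (internal files and
#'   returned objects keep full precision).
#' @param map_format `"png"`, `"svg"` or `"text"` for the cluster maps.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, preset = "festuca_like",
                            out = "mycopattern-report", alpha = 0.05,
                            k_clusters = 9, seed = 42,
                            histogram = c("both", "best_fitted",
                                          "class_restricted"),
                            rounding = 2,
                            map_format = c("png", "svg", "text")) {
  stopifnot(alpha > 0, alpha < 1, k_clusters >= 1, rounding >= 0)
  structure(list(input = input, preset = preset, out = out, alpha = alpha,
                 k_clusters = as.integer(k_clusters),
                 seed = as.integer(seed),
                 histogram = match.arg(histogram),
                 rounding = as.integer(rounding),
                 map_format = match.arg(map_format)),
            class = "pipeline_config")
}

#' Validate a grid-table file
#'
#' Checks the schema (required columns), value ranges (codes 0..6,
#' row/col 1..10), duplicate cell entries, and the sampling-design counts.
#' Structural problems are errors; an incomplete design (e.g. a missing
#' microscopic field) is only a warning, since the analysis pools
#' whatever was observed.
#'
#' @param path Path to the CSV file.
#' @param expected_fields Expected fields per segment for the design
#'   check (default 15); `NULL` skips it.
#' @return List of class `validation_report` with character vectors
#'   `errors` and `warnings` and the logical `ok` (`TRUE` when there are
#'   no errors).
#' @export
validate_inputs <- function(path, expected_fields = 15) {
  if (!file.exists(path)) stop("file not found: ", path)
  errors <- character(); warnings_out <- character()
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) e)
  if (inherits(df, "error")) {
    errors <- c(errors, paste("unreadable CSV:", conditionMessage(df)))
    return(structure(list(errors = errors, warnings = warnings_out,
                          ok = FALSE), class = "validation_report"))
  }
  required <- c("replication", "segment", "field", "row", "col", "code")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    errors <- c(errors, paste("missing column(s):",
                              paste(missing, collapse = ", ")))
  } else if (nrow(df) > 0) {
    line <- seq_len(nrow(df)) + 1L
    bad <- which(!(df$code %in% 0:6))
    if (length(bad))
      errors <- c(errors, paste0("code outside 0..6 at line(s) ",
                                 paste(line[bad], collapse = ", ")))
    bad <- which(df$row < 1 | df$row > 10 | df$col < 1 | df$col > 10)
    if (length(bad))
      errors <- c(errors, paste0("row/col outside 1..10 at line(s) ",
                                 paste(line[bad], collapse = ", ")))
    key <- paste(df$replication, df$segment, df$field, df$row, df$col)
    dup <- which(duplicated(key))
    if (length(dup)) {
      for (d in dup[seq_len(min(5, length(dup)))]) {
        first <- line[match(key[d], key)]
        errors <- c(errors, paste0("duplicate cell entry at lines ", first,
                                   " and ", line[d]))
      }
    }
    if (!is.null(expected_fields) && length(errors) == 0) {
      per_seg <- dplyr::summarise(
        dplyr::group_by(tibble::as_tibble(df), .data$replication,
                        .data$segment),
        n_fields = dplyr::n_distinct(.data$field), .groups = "drop")
      short <- per_seg[per_seg$n_fields < expected_fields, ]
      if (nrow(short))
        warnings_out <- c(warnings_out, sprintf(
          "replication %d segment %d has %d of %d fields (design incomplete)",
          short$replication, short$segment, short$n_fields,
          expected_fields))
    }
  }
  structure(list(errors = errors, warnings = warnings_out,
                 ok = length(errors) == 0),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s: %d error(s), %d warning(s)\n",
              if (x$ok) "OK" else "FAILED", length(x$errors),
              length(x$warnings)))
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

.round_cols <- function(df, digits) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

.stage <- function(name, expr) {
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
  res
}

#' Run the full colonization analysis pipeline
#'
#' Orchestrates every stage: load (or simulate) coded grids, compute the
#' per-observation index table, summarize the five frequency classes with
#' ANOVA and protected-LSD letters, fit the five pairwise regressions
#' (frequency to intensity, frequency/intensity/colonization degree to
#' arbuscules, colonization degree to the mycorrhizal ratio), run PCA and
#' NMDS ordinations, cut segment-level mean records into strategy
#' clusters, and export one representative colonization map per cluster.
#' All randomness (simulation, NMDS restarts) is controlled by
#' `config$seed`, so a fixed configuration reproduces the output bundle
#' byte for byte.
#'
#' Files written to `config$out`: `indices.csv`, `class_summary.csv`
#' (class, parameter, mean, se, n, letter, with F/p footer rows),
#' `histograms.csv`, `regressions.csv`, `ordination_pca.csv`,
#' `ordination_nmds.csv`, `cluster_centroids.csv`,
#' `cluster_assignment.csv`, `maps/C*.{png,svg,txt}` and `run_log.txt`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the computed objects (`records`,
#'   `class_summary`, `anova`, `regressions`, `pca`, `nmds`, `clusters`,
#'   `report`, `out`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("mycopattern run log",
                 paste("package version:",
                       as.character(utils::packageVersion("mycopattern"))),
                 paste("seed:", config$seed),
                 paste("alpha:", config$alpha),
                 paste("k_clusters:", config$k_clusters))

  grids <- .stage("load", {
    if (!is.null(config$input)) {
      v <- validate_inputs(config$input)
      if (!v$ok) stop("input validation failed: ",
                      paste(v$errors, collapse = "; "))
      read_grid_table(config$input)
    } else {
      simulate_dataset(colonization_preset(config$preset,
                                           seed = config$seed))
    }
  })
  if (length(grids) == 0) stop("pipeline stage 'load' failed: no grids")
  n_seg <- nrow(unique(data.frame(
    r = vapply(grids, `[[`, 1L, "replication"),
    s = vapply(grids, `[[`, 1L, "segment"))))
  log_lines <- c(log_lines, sprintf("grids: %d over %d segments",
                                    length(grids), n_seg))

  records <- .stage("indices", compute_indices_table(grids))
  utils::write.csv(records, file.path(config$out, "indices.csv"),
                   row.names = FALSE)

  class_summary <- .stage("classes", {
    withCallingHandlers(summarize_by_class(records),
                        warning = function(w) {
                          log_lines <<- c(log_lines,
                                          paste("warning:",
                                                conditionMessage(w)))
                          invokeRestart("muffleWarning")
                        })
  })
  present <- unique(as.character(class_summary$freq_class))
  anova_res <- list()
  if (length(present) >= 2 &&
      min(table(records$freq_class)[present]) >= 2) {
    anova_res <- .stage("anova", {
      params <- intersect(.index_cols, names(records))
      out <- lapply(params, function(p)
        suppressWarnings(anova_lsd(records, p, alpha = config$alpha)))
      names(out) <- params
      out
    })
  } else {
    log_lines <- c(log_lines,
                   "anova skipped: fewer than 2 populated classes")
  }
  cs <- class_summary
  if (length(anova_res)) {
    lets <- dplyr::bind_rows(lapply(anova_res, function(a) {
      tibble::tibble(freq_class = a$table$group, parameter = a$parameter,
                     letter = a$table$letter)
    }))
    cs <- dplyr::left_join(
      dplyr::mutate(cs, freq_class = as.character(.data$freq_class)),
      lets, by = c("freq_class", "parameter"))
    foot <- dplyr::bind_rows(lapply(anova_res, function(a) {
      tibble::tibble(freq_class = c("F_test", "p_value"),
                     parameter = a$parameter, mean = c(a$F, a$p),
                     se = NA_real_, n = NA_integer_,
                     letter = NA_character_)
    }))
    cs <- dplyr::bind_rows(cs, foot)
  }
  utils::write.csv(.round_cols(as.data.frame(cs), config$rounding),
                   file.path(config$out, "class_summary.csv"),
                   row.names = FALSE, na = "")

  hist_sol <- switch(config$histogram, both = c("best_fitted",
                                                "class_restricted"),
                     config$histogram)
  hists <- .stage("histograms", {
    dplyr::bind_rows(lapply(intersect(.index_cols, names(records)),
                            function(p) {
      dplyr::bind_rows(lapply(hist_sol, function(s) {
        h <- col_histogram(records, p, s)
        tibble::tibble(parameter = p, solution = s,
                       bin_low = h$breaks[-length(h$breaks)],
                       bin_high = h$breaks[-1], count = h$counts)
      }))
    }))
  })
  utils::write.csv(hists, file.path(config$out, "histograms.csv"),
                   row.names = FALSE)

  regressions <- .stage("regressions", {
    out <- lapply(.regression_pairs(), function(pr) {
      if (stats::var(records[[pr[1]]]) == 0) {
        log_lines <<- c(log_lines, sprintf(
          "regression %s -> %s skipped: constant predictor",
          pr[1], pr[2]))
        return(NULL)
      }
      fit_regression(records, pr[1], pr[2])
    })
    names(out) <- vapply(.regression_pairs(),
                         function(pr) paste(pr, collapse = "_to_"), "")
    out[!vapply(out, is.null, TRUE)]
  })
  reg_tbl <- dplyr::bind_rows(lapply(regressions, function(r)
    tibble::tibble(predictor = r$predictor, response = r$response,
                   intercept = r$intercept, slope = r$slope,
                   sigma = r$sigma, r_squared = r$r_squared)))
  utils::write.csv(.round_cols(as.data.frame(reg_tbl), 4),
                   file.path(config$out, "regressions.csv"),
                   row.names = FALSE)

  ord_degenerate <- all(vapply(intersect(.index_cols, names(records)),
                               function(v) stats::var(records[[v]]) == 0,
                               TRUE))
  pca_res <- NULL; nmds_res <- NULL
  if (ord_degenerate) {
    log_lines <- c(log_lines, "ordination skipped: constant indices")
  } else {
    pca_res <- .stage("pca", suppressWarnings(pca_indices(records)))
    pca_scores <- tibble::tibble(
      replication = records$replication, segment = records$segment,
      field = records$field,
      axis1 = pca_res$scores[, 1], axis2 = pca_res$scores[, 2],
      freq_class = as.character(records$freq_class))
    utils::write.csv(pca_scores,
                     file.path(config$out, "ordination_pca.csv"),
                     row.names = FALSE)
    nmds_res <- .stage("nmds",
                       nmds_indices(records, seed = config$seed))
    nmds_scores <- tibble::tibble(
      replication = records$replication, segment = records$segment,
      field = records$field,
      axis1 = nmds_res$scores[, 1], axis2 = nmds_res$scores[, 2],
      freq_class = as.character(records$freq_class))
    utils::write.csv(nmds_scores,
                     file.path(config$out, "ordination_nmds.csv"),
                     row.names = FALSE)
    log_lines <- c(log_lines,
                   sprintf("pca variance axis1+axis2: %.2f",
                           sum(pca_res$var_pct[1:2])),
                   sprintf("nmds stress: %.4f", nmds_res$stress))
  }

  clusters <- .stage("clusters", {
    seg_means <- dplyr::summarise(
      dplyr::group_by(records, .data$replication, .data$segment),
      dplyr::across(dplyr::all_of(intersect(.index_cols, names(records))),
                    mean),
      .groups = "drop")
    if (config$k_clusters > nrow(seg_means))
      stop("k_clusters exceeds the number of segments")
    cluster_strategies(seg_means, k = config$k_clusters)
  })
  utils::write.csv(.round_cols(as.data.frame(clusters$centroids),
                               config$rounding),
                   file.path(config$out, "cluster_centroids.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(clusters$assignment[,
                     c("replication", "segment", "cluster")]),
                   file.path(config$out, "cluster_assignment.csv"),
                   row.names = FALSE)

  report <- .stage("report", strategy_report(clusters, grids))
  map_dir <- file.path(config$out, "maps")
  dir.create(map_dir, showWarnings = FALSE)
  ext <- switch(config$map_format, png = "png", svg = "svg", text = "txt")
  for (cl in report$clusters) {
    if (is.null(cl$map)) {
      log_lines <- c(log_lines,
                     sprintf("cluster %s: no grid data, map skipped",
                             cl$cluster))
      next
    }
    export_map_image(cl$map,
                     file.path(map_dir, paste0(cl$cluster, ".", ext)),
                     format = config$map_format)
  }
  log_lines <- c(log_lines,
                 sprintf("clusters: %d; maps written: %d",
                         clusters$k,
                         sum(!vapply(report$clusters,
                                     function(cl) is.null(cl$map), TRUE))))
  writeLines(log_lines, file.path(config$out, "run_log.txt"))
  invisible(list(records = records, class_summary = class_summary,
                 anova = anova_res, regressions = regressions,
                 pca = pca_res, nmds = nmds_res, clusters = clusters,
                 report = report, out = config$out))
}
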