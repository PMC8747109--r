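#' Complement and ratio identities of colonization intensity
#'
#' The non-mycorrhizal area is the exact complement of intensity,
#' `100 - I`, and the mycorrhizal/non-mycorrhizal report is
#' `I / (100 - I)`. A fully colonized field (I = 100) would divide by
#' zero; it is reported as the capped sentinel 99 with a warning.
#'
#' @param intensity_pct Intensity of colonization, percent in \[0, 100\].
#' @return `non_mycorrhizal_pct()`: the complementary percentage.
#' @export
#' @examples
#' non_mycorrhizal_pct(13.17)  # 86.83
#' m_nonm_ratio(3.59)          # ~0.037
non_mycorrhizal_pct <- function(intensity_pct) {
  stopifnot(all(intensity_pct >= 0 & intensity_pct <= 100))
  100 - intensity_pct
}

#' @rdname non_mycorrhizal_pct
#' @return `m_nonm_ratio()`: the mycorrhizal/non-mycorrhizal area ratio.
#' @export
m_nonm_ratio <- function(intensity_pct) {
  stopifnot(all(intensity_pct >= 0 & intensity_pct <= 100))
  full <- intensity_pct >= 100
  if (any(full))
    warning("fully colonized observation(s): ratio capped at sentinel 99")
  ifelse(full, 99, intensity_pct / (100 - intensity_pct))
}

#' Compute the seven colonization indices of one microscopic field
#'
#' From a 10 x 10 coded grid:
#' * frequency `F` = 10 x number of grid columns (positions along the root
#'   axis) containing at least one fungal structure — the root's primary
#'   permissiveness;
#' * intensity `I` = number of occupied cells (out of 100) — secondary
#'   permissiveness;
#' * arbuscule and vesicle abundance = counts of codes 2 and 3 (percent of
#'   all cells);
#' * colonization degree = `F * I / 100`, the volumetric synthesis of the
#'   two;
#' * non-mycorrhizal area = `100 - I`;
#' * mycorrhizal/non-mycorrhizal report = `I / (100 - I)`.
#'
#' Since an occupied column holds at most 10 occupied cells, `I <= F`
#' always.
#'
#' @param grid A [colonization_grid()].
#' @return One-row [tibble::tibble] with columns `replication`, `segment`,
#'   `field`, `frequency`, `intensity`, `arbuscules`, `vesicles`,
#'   `colonization_degree`, `non_mycorrhizal`, `m_nonm_ratio`.
#' @export
#' @examples
#' g <- colonization_grid(1, 1, 1)
#' g$cells[, 1] <- 1L          # one fully hyphal column
#' compute_indices(g)          # F = 10, I = 10
compute_indices <- function(grid) {
  stopifnot(inherits(grid, "colonization_grid"))
  occ <- grid$cells != 0L
  f <- 10 * sum(colSums(occ) > 0)
  i <- sum(occ)
  tibble::tibble(
    replication = grid$replication,
    segment = grid$segment,
    field = grid$field,
    frequency = as.numeric(f),
    intensity = as.numeric(i),
    arbuscules = as.numeric(sum(grid$cells == 2L)),
    vesicles = as.numeric(sum(grid$cells == 3L)),
    colonization_degree = f * i / 100,
    non_mycorrhizal = non_mycorrhizal_pct(i),
    m_nonm_ratio = m_nonm_ratio(i)
  )
}

#' Compute the index table for a collection of grids
#'
#' @param grids List of [colonization_grid()] objects.
#' @return Tibble with one [compute_indices()] row per grid plus the
#'   `freq_class` column from [assign_class()].
#' @export
compute_indices_table <- function(grids) {
  stopifnot(length(grids) > 0)
  out <- dplyr::bind_rows(lapply(grids, compute_indices))
  out$freq_class <- assign_class(out$frequency)
  out
}

#' Frequency classes M1-M5
#'
#' Colonization frequency is binned into five 20-percent-wide classes used
#' as the coding variable of the analysis: M1 (low) = \[0, 20\],
#' M2 (medium-low) = (20, 40\], M3 (medium) = (40, 60\],
#' M4 (medium-high) = (60, 80\], M5 (high) = (80, 100\]. The intervals are
#' half-open at the left so that the partition is total for non-integer
#' frequencies; an exact 20 falls in M1.
#'
#' @param frequency_pct Numeric vector of frequencies in \[0, 100\].
#' @return Ordered factor with levels M1..M5.
#' @export
#' @examples
#' assign_class(c(0, 6.55, 20, 20.5, 92.69, 100))
assign_class <- function(frequency_pct) {
  if (any(is.na(frequency_pct)) ||
      any(frequency_pct < 0 | frequency_pct > 100))
    stop("frequency must lie in [0, 100]")
  cut(frequency_pct, breaks = c(0, 20, 40, 60, 80, 100),
      labels = paste0("M", 1:5), include.lowest = TRUE, right = TRUE,
      ordered_result = TRUE)
}

#' Class boundaries of the five frequency classes
#'
#' @return Tibble with columns `label`, `lower_pct`, `upper_pct`.
#' @export
class_bounds <- function() {
  tibble::tibble(label = paste0("M", 1:5),
                 lower_pct = c(0, 20, 40, 60, 80),
                 upper_pct = c(20, 40, 60, 80, 100))
}

.index_cols <- c("frequency", "intensity", "arbuscules", "vesicles",
                 "colonization_degree", "non_mycorrhizal", "m_nonm_ratio")

#' Aggregate colonization records by a grouping key
#'
#' Returns, per group and per index, the arithmetic mean, the standard
#' error of the mean (sample sd / sqrt(n); 0 for n = 1) and the group
#' count.
#'
#' @param records Tibble of colonization records
#'   (see [compute_indices_table()]).
#' @param by Character vector of grouping column names present in
#'   `records` (e.g. `"freq_class"`, `"segment"`).
#' @param parameters Index columns to aggregate; defaults to all seven.
#' @return Long tibble with columns `by` ..., `parameter`, `mean`, `se`,
#'   `n`.
#' @export
aggregate_indices <- function(records, by,
                              parameters = intersect(.index_cols,
                                                     names(records))) {
  stopifnot(nrow(records) > 0, length(by) > 0, all(by %in% names(records)),
            length(parameters) > 0, all(parameters %in% names(records)))
  long <- tidyr_pivot(records, by, parameters)
  out <- dplyr::summarise(
    dplyr::group_by(long, dplyr::across(dplyr::all_of(c(by, "parameter")))),
    mean = mean(.data$value),
    se = if (dplyr::n() > 1) stats::sd(.data$value) / sqrt(dplyr::n()) else 0,
    n = dplyr::n(),
    .groups = "drop"
  )
  out$parameter <- factor(out$parameter, levels = parameters)
  dplyr::arrange(out, dplyr::across(dplyr::all_of(by)), .data$parameter)
}

# minimal long-format reshape (avoids a tidyr dependency)
tidyr_pivot <- function(records, by, parameters) {
  pieces <- lapply(parameters, function(p) {
    d <- records[, by, drop = FALSE]
    d$parameter <- p
    d$value <- records[[p]]
    d
  })
  dplyr::bind_rows(pieces)
}

#' Summarize colonization records by frequency class
#'
#' Bins records into classes M1-M5 via [assign_class()] and aggregates
#' each index (mean, standard error, n) per class. Classes with zero
#' members are omitted with a warning.
#'
#' @inheritParams aggregate_indices
#' @return Long tibble with columns `freq_class`, `parameter`, `mean`,
#'   `se`, `n`.
#' @export
summarize_by_class <- function(records,
                               parameters = intersect(.index_cols,
                                                      names(records))) {
  stopifnot(nrow(records) > 0, "frequency" %in% names(records))
  if (!"freq_class" %in% names(records))
    records$freq_class <- assign_class(records$frequency)
  present <- levels(records$freq_class)[levels(records$freq_class) %in%
                                          unique(records$freq_class)]
  absent <- setdiff(paste0("M", 1:5), present)
  if (length(absent))
    warning("no observations in class(es): ", paste(absent, collapse = ", "))
  records$freq_class <- droplevels(records$freq_class)
  aggregate_indices(records, by = "freq_class", parameters = parameters)
}
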