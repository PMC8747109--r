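# shared fixtures: random coded grids and an independent brute-force
# index oracle (loops over every cell/column, no shortcuts)

random_grid <- function(replication = 1, segment = 1, field = 1,
                        p_occupied = 0.3) {
  codes <- sample(0:6, 100, replace = TRUE,
                  prob = c(1 - p_occupied, rep(p_occupied / 6, 6)))
  colonization_grid(replication, segment, field, matrix(codes, 10, 10))
}

oracle_indices <- function(grid) {
  cells <- grid$cells
  occupied_cols <- 0
  for (j in 1:10) {
    any_occ <- FALSE
    for (i in 1:10) if (cells[i, j] != 0) any_occ <- TRUE
    if (any_occ) occupied_cols <- occupied_cols + 1
  }
  occ <- 0; arb <- 0; ves <- 0
  for (i in 1:10) for (j in 1:10) {
    if (cells[i, j] != 0) occ <- occ + 1
    if (cells[i, j] == 2) arb <- arb + 1
    if (cells[i, j] == 3) ves <- ves + 1
  }
  f <- 10 * occupied_cols
  list(frequency = f, intensity = occ, arbuscules = arb, vesicles = ves,
       colonization_degree = f * occ / 100,
       non_mycorrhizal = 100 - occ,
       m_nonm_ratio = if (occ >= 100) 99 else occ / (100 - occ))
}

# closed-form one-way ANOVA F statistic (textbook sums of squares)
oracle_anova_f <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  levs <- unique(groups)
  ss_b <- sum(vapply(levs, function(g)
    sum(groups == g) * (mean(values[groups == g]) - grand)^2, 1))
  ss_w <- sum(vapply(levs, function(g)
    sum((values[groups == g] - mean(values[groups == g]))^2), 1))
  df_b <- length(levs) - 1
  df_w <- length(values) - length(levs)
  (ss_b / df_b) / (ss_w / df_w)
}

# normal-equation OLS oracle
oracle_ols <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# exhaustive pooled-variance pairwise t-tests (Fisher's LSD), returning
# a logical matrix of significant differences over sorted group names
oracle_lsd_pairs <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  levs <- sort(unique(groups))
  k <- length(levs)
  n <- length(values)
  ss_w <- sum(vapply(levs, function(g)
    sum((values[groups == g] - mean(values[groups == g]))^2), 1))
  mse <- ss_w / (n - k)
  out <- matrix(FALSE, k, k, dimnames = list(levs, levs))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (b <= a) next
    na <- sum(groups == levs[a]); nb <- sum(groups == levs[b])
    tt <- (mean(values[groups == levs[a]]) -
             mean(values[groups == levs[b]])) /
      sqrt(mse * (1 / na + 1 / nb))
    p <- 2 * stats::pt(-abs(tt), n - k)
    out[a, b] <- out[b, a] <- p < alpha
  }
  out
}
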