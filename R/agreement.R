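# Reliability statistics for ordinal skin tone ratings and repeated
# continuous measurements. Weighted kappa and ICC(2,1) are computed from
# their definitions (observed/expected weighted proportions; ANOVA mean
# squares); the classical paired t and Pearson chi-squared go through stats.

#' Linear-weighted Cohen's kappa
#'
#' Chance-corrected agreement for two raters on a shared ordered scale of
#' `k` levels, with disagreement weights `w_ij = |i - j| / (k - 1)`:
#' `kappa = 1 - sum(w * O) / sum(w * E)`, where `O` holds observed pair
#' proportions and `E` the products of the two raters' marginals. The weight
#' grid always spans the full `1..k` scale, so unobserved levels do not
#' change the weighting.
#'
#' @param rating_a,rating_b Integer ratings in `1..k`, same length.
#' @param k Number of scale levels (e.g. 10 for MST, 6 for FST).
#' @return Kappa in `[-1, 1]`. When both raters use a single identical
#'   category throughout, chance agreement is total and kappa is undefined:
#'   `NA` is returned with a `tonescale_degenerate_marginals` warning.
#' @examples
#' linear_weighted_kappa(c(1, 2, 3), c(1, 2, 3), k = 3) # 1
#' @export
linear_weighted_kappa <- function(rating_a, rating_b, k) {
  stopifnot(length(rating_a) == length(rating_b), k >= 2)
  keep <- !is.na(rating_a) & !is.na(rating_b)
  rating_a <- rating_a[keep]
  rating_b <- rating_b[keep]
  n <- length(rating_a)
  if (n < 2) stop_tonescale("need at least 2 rating pairs", "too_few_pairs")
  if (any(rating_a < 1 | rating_a > k | rating_b < 1 | rating_b > k)) {
    stop_tonescale("ratings must lie in 1..k", "invalid_rating")
  }
  O <- table(factor(rating_a, levels = 1:k),
             factor(rating_b, levels = 1:k)) / n
  E <- outer(rowSums(O), colSums(O))
  w <- abs(outer(1:k, 1:k, "-")) / (k - 1)
  we <- sum(w * E)
  if (we == 0) {
    warn_tonescale("all ratings identical on both sides; kappa undefined",
                   "degenerate_marginals")
    return(NA_real_)
  }
  1 - sum(w * O) / we
}

#' Intraclass correlation for repeated measurements, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC from
#' the ANOVA mean squares of a subjects x repeats matrix: with `MSR` the
#' between-subject, `MSC` the between-repeat and `MSE` the residual mean
#' square over `n` subjects and `m` repeats,
#' `ICC = (MSR - MSE) / (MSR + (m - 1) MSE + m (MSC - MSE) / n)`.
#' This is the standard form for asking whether repeated device
#' measurements agree in absolute value, e.g. colorimeter triplicates of
#' ITA at the same site.
#'
#' @param rm Numeric matrix, `n >= 2` subjects (rows) by `m >= 2` repeats
#'   (columns), no missing cells.
#' @return ICC in `(-1, 1]`.
#' @export
icc_agreement <- function(rm) {
  rm <- as.matrix(rm)
  if (anyNA(rm)) stop_tonescale("no missing cells allowed", "missing_cells")
  n <- nrow(rm)
  m <- ncol(rm)
  if (n < 2 || m < 2) {
    stop_tonescale("need >= 2 subjects and >= 2 repeats", "too_few")
  }
  grand <- mean(rm)
  row_m <- rowMeans(rm)
  col_m <- colMeans(rm)
  msr <- m * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (m - 1)
  sse <- sum((rm - outer(row_m, rep(1, m)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (m - 1))
  if (msr == 0) {
    stop_tonescale("no between-subject variance; ICC undefined",
                   "zero_variance")
  }
  (msr - mse) / (msr + (m - 1) * mse + m * (msc - mse) / n)
}

#' Paired mean difference with t-based inference
#'
#' Classical paired t-test on `y - x` with a 95 percent t confidence
#' interval. Identical vectors return a zero difference with `p = 1` by
#' convention; a constant nonzero difference has no sampling variance and
#' raises `tonescale_zero_variance_differences`.
#'
#' @param x,y Paired numeric vectors of equal length `>= 2`.
#' @param conf_level Confidence level, default 0.95.
#' @return A list with `mean_difference`, `conf_int` (length 2), `p_value`,
#'   `t`, `df`, `n`.
#' @export
paired_mean_difference <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 2) stop_tonescale("need >= 2 pairs", "too_few_pairs")
  d <- y - x
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(mean_difference = 0, conf_int = c(0, 0), p_value = 1,
                  t = 0, df = length(d) - 1, n = length(d)))
    }
    stop_tonescale("differences have zero variance", "zero_variance_differences")
  }
  tt <- stats::t.test(y, x, paired = TRUE, conf.level = conf_level)
  list(mean_difference = unname(tt$estimate), conf_int = unname(tt$conf.int),
       p_value = tt$p.value, t = unname(tt$statistic),
       df = unname(tt$parameter), n = length(d))
}

#' Pearson chi-squared test of independence
#'
#' `sum((O - E)^2 / E)` over an `r x c` contingency table, with expected
#' counts from the marginals and `(r - 1)(c - 1)` degrees of freedom. No
#' continuity correction.
#'
#' @param tab Matrix of nonnegative counts with positive total.
#' @return List with `statistic`, `dof`, `p_value`, `expected`.
#' @export
chi_squared_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || sum(tab) <= 0) {
    stop_tonescale("counts must be nonnegative with positive total",
                   "invalid_table")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    stop_tonescale("a marginal is zero: drop empty rows/columns first",
                   "zero_expected")
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), dof = unname(res$parameter),
       p_value = res$p.value, expected = expected)
}

#' Per-class and overall percent concordance
#'
#' For a `k x k` contingency table of reference class (rows) against
#' assigned class (columns): per-class concordance is the diagonal count
#' over the row total (in percent, `NA` for empty rows); overall is the
#' trace over the grand total.
#'
#' @param tab Square matrix of nonnegative counts.
#' @return List with `per_class` (percent, named by row) and `overall`.
#' @export
concordance_by_class <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab)) stop_tonescale("table must be square", "invalid_table")
  if (sum(tab) <= 0) stop_tonescale("empty table", "invalid_table")
  row_tot <- rowSums(tab)
  per <- ifelse(row_tot > 0, diag(tab) / row_tot * 100, NA_real_)
  names(per) <- rownames(tab)
  list(per_class = per, overall = sum(diag(tab)) / sum(tab) * 100)
}

#' Agreement statistic stratified by anatomic site
#'
#' Computes one linear-weighted kappa per anatomic site, plus a
#' lesional-only row and a pooled all-sites row (the pooled statistic on
#' all pairs, not a mean of per-site values) -- the layout of an
#' inter-rater agreement heatmap. Sites with fewer than 2 complete pairs
#' are reported as `NA`.
#'
#' @param data Data frame with columns `rating_a`, `rating_b`,
#'   `anatomic_site`, `lesional` (logical).
#' @param k Scale size passed to [linear_weighted_kappa()].
#' @return Tibble with columns `stratum`, `kappa`, `n`.
#' @export
agreement_by_site <- function(data, k) {
  stopifnot(all(c("rating_a", "rating_b", "anatomic_site", "lesional") %in%
                  names(data)))
  ok <- !is.na(data$rating_a) & !is.na(data$rating_b)
  data <- data[ok, , drop = FALSE]
  kap <- function(d) {
    if (nrow(d) < 2) return(NA_real_)
    suppressWarnings(linear_weighted_kappa(d$rating_a, d$rating_b, k))
  }
  sites <- sort(unique(data$anatomic_site[!data$lesional]))
  rows <- lapply(sites, function(s) {
    d <- data[!data$lesional & data$anatomic_site == s, , drop = FALSE]
    tibble::tibble(stratum = s, kappa = kap(d), n = nrow(d))
  })
  les <- data[data$lesional, , drop = FALSE]
  rows <- c(rows, list(
    tibble::tibble(stratum = "lesional", kappa = kap(les), n = nrow(les)),
    tibble::tibble(stratum = "all_sites", kappa = kap(data), n = nrow(data))
  ))
  dplyr::bind_rows(rows)
}
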