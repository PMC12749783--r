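# Fairness auditing of classifier malignancy scores across skin tone
# classes: ECDF comparisons via the two-sample KS statistic, pooled
# percentile ranks per class, and the KS-by-class-distance summary. The
# classifier is treated as an exchangeable score source read from a table.

#' Log-transform malignancy scores
#'
#' Natural log with a small floor so that zero scores map to `log(floor)`
#' rather than `-Inf`. The KS statistic is invariant under this (strictly
#' monotone) transform; it matters only for plotting.
#'
#' @param scores Numeric scores on the 0-100 percent scale.
#' @param floor_eps Floor applied before the log, default `1e-4`.
#' @return `log(pmax(scores, floor_eps))`.
#' @export
log_scores <- function(scores, floor_eps = 1e-4) {
  if (any(scores < 0, na.rm = TRUE)) {
    stop_tonescale("scores must be nonnegative", "invalid_scores")
  }
  log(pmax(scores, floor_eps))
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' `D = sup_t |ECDF_x(t) - ECDF_y(t)|`, evaluated over the pooled sample
#' points. Ties are handled exactly (both ECDFs jump at a shared value).
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `D` in `[0, 1]`, `p_value` (asymptotic two-sample
#'   approximation), `n_x`, `n_y`.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    stop_tonescale("both samples must be non-empty", "empty_sample")
  }
  pooled <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(pooled)
  Fy <- stats::ecdf(y)(pooled)
  D <- max(abs(Fx - Fy))
  n <- length(x) * length(y) / (length(x) + length(y))
  # asymptotic Kolmogorov tail: Q(lambda) = 2 sum (-1)^(k-1) exp(-2 k^2 lambda^2)
  lambda <- (sqrt(n) + 0.12 + 0.11 / sqrt(n)) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  list(D = D, p_value = min(max(p, 0), 1),
       n_x = length(x), n_y = length(y))
}

#' Per-class mean percentile rank of pooled scores
#'
#' Each score's percentile within the pooled sample is `(midrank - 0.5) /
#' n * 100`; the function returns the mean percentile per class. A class
#' scoring systematically higher than the rest has a mean rank above 50.
#'
#' @param scores Numeric scores.
#' @param classes Class label per score.
#' @return Tibble with `class`, `mean_rank` (0-100), `n`.
#' @export
percentile_ranks <- function(scores, classes) {
  keep <- !is.na(scores) & !is.na(classes)
  scores <- scores[keep]
  classes <- classes[keep]
  if (length(scores) == 0) stop_tonescale("no scores", "empty_sample")
  pct <- (rank(scores, ties.method = "average") - 0.5) / length(scores) * 100
  agg <- tapply(pct, classes, mean)
  tibble::tibble(class = names(agg), mean_rank = as.numeric(agg),
                 n = as.integer(table(classes)[names(agg)]))
}

#' Mean KS statistic by ordinal class distance
#'
#' For every ordered-class pair `(i, j)` with data, computes the pairwise
#' two-sample KS statistic, then averages over pairs at each distance
#' `delta = |i - j| >= 1`. A scale whose classes track the score
#' distribution shows mean D rising with delta.
#'
#' @param scores Numeric scores.
#' @param classes Integer class index per score.
#' @return List with `pairs` (tibble: `class_i`, `class_j`, `delta`, `D`)
#'   and `by_delta` (tibble: `delta`, `mean_D`, `n_pairs`).
#' @export
ks_by_class_distance <- function(scores, classes) {
  keep <- !is.na(scores) & !is.na(classes)
  scores <- scores[keep]
  classes <- as.integer(classes[keep])
  lev <- sort(unique(classes))
  if (length(lev) < 2) stop_tonescale("need >= 2 classes with scores",
                                      "too_few_classes")
  combs <- utils::combn(lev, 2)
  pairs <- dplyr::bind_rows(lapply(seq_len(ncol(combs)), function(p) {
    i <- combs[1, p]; j <- combs[2, p]
    D <- ks_two_sample(scores[classes == i], scores[classes == j])$D
    tibble::tibble(class_i = i, class_j = j, delta = j - i, D = D)
  }))
  by_delta <- dplyr::summarise(dplyr::group_by(pairs, .data$delta),
                               mean_D = mean(.data$D),
                               n_pairs = dplyr::n(), .groups = "drop")
  list(pairs = pairs, by_delta = by_delta)
}

#' Fairness report for one labeling scheme
#'
#' Bundles the per-class ECDF comparison for one scale: the pairwise KS
#' matrix, mean percentile ranks, and the KS-by-distance summary.
#'
#' @param scores Numeric malignancy scores (0-100 percent).
#' @param classes Integer class per score (e.g. MST 1-10 or FST 1-6).
#' @param scale Scheme name for printing.
#' @return Object of class `fairness_report`: list with `scale`,
#'   `ks_matrix` (symmetric, zero diagonal, `NA` for absent classes),
#'   `percentiles`, `by_delta`, `pairs`, `n`.
#' @export
fairness_report <- function(scores, classes, scale = "scale") {
  keep <- !is.na(scores) & !is.na(classes)
  scores <- scores[keep]
  classes <- as.integer(classes[keep])
  kd <- ks_by_class_distance(scores, classes)
  lev <- sort(unique(classes))
  k <- max(lev)
  M <- matrix(NA_real_, k, k, dimnames = list(1:k, 1:k))
  for (l in lev) M[l, l] <- 0
  for (p in seq_len(nrow(kd$pairs))) {
    i <- kd$pairs$class_i[p]; j <- kd$pairs$class_j[p]
    M[i, j] <- M[j, i] <- kd$pairs$D[p]
  }
  structure(list(scale = scale, ks_matrix = M,
                 percentiles = percentile_ranks(scores, classes),
                 by_delta = kd$by_delta, pairs = kd$pairs,
                 n = length(scores)),
            class = "fairness_report")
}

#' @export
print.fairness_report <- function(x, ...) {
  cat(sprintf("<fairness_report> %s: %d scores, %d classes\n",
              x$scale, x$n, nrow(x$percentiles)))
  cat("  mean KS by class distance:\n")
  print(as.data.frame(x$by_delta), row.names = FALSE)
  invisible(x)
}

#' ECDF plot of log-transformed scores by class
#'
#' @param scores,classes As in [fairness_report()].
#' @param log_transform Apply [log_scores()] first (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_score_ecdf <- function(scores, classes, log_transform = TRUE) {
  s <- if (log_transform) log_scores(scores) else scores
  df <- tibble::tibble(score = s, class = factor(classes))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, color = .data$class)) +
    ggplot2::stat_ecdf(linewidth = 0.5) +
    ggplot2::labs(x = if (log_transform) "log score" else "score",
                  y = "cumulative fraction") +
    ggplot2::theme_minimal()
}

#' KS-by-distance plot
#'
#' Pairwise KS statistics against ordinal class distance, with the per-delta
#' mean overlaid.
#'
#' @param report A [fairness_report()].
#' @return A ggplot object.
#' @export
plot_ks_by_distance <- function(report) {
  ggplot2::ggplot(report$pairs,
                  ggplot2::aes(x = .data$delta, y = .data$D)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = report$by_delta,
                       ggplot2::aes(y = .data$mean_D), color = "red") +
    ggplot2::labs(title = report$scale, x = "class distance",
                  y = "KS statistic") +
    ggplot2::theme_minimal()
}
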