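# Definition-level brute-force oracles, written as plain loops so they stay
# independent of the vectorised implementations they check.

# linear-weighted kappa by enumerating every table cell
oracle_kappa <- function(a, b, k) {
  n <- length(a)
  obs <- 0
  exp_ <- 0
  for (i in 1:k) {
    for (j in 1:k) {
      w <- abs(i - j) / (k - 1)
      o_ij <- sum(a == i & b == j) / n
      e_ij <- (sum(a == i) / n) * (sum(b == j) / n)
      obs <- obs + w * o_ij
      exp_ <- exp_ + w * e_ij
    }
  }
  1 - obs / exp_
}

# ICC(2,1) from explicitly accumulated ANOVA sums of squares
oracle_icc <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  grand <- mean(m)
  ss_subj <- 0
  for (i in 1:n) ss_subj <- ss_subj + k * (mean(m[i, ]) - grand)^2
  ss_col <- 0
  for (j in 1:k) ss_col <- ss_col + n * (mean(m[, j]) - grand)^2
  ss_err <- 0
  for (i in 1:n) for (j in 1:k) {
    ss_err <- ss_err + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + grand)^2
  }
  msr <- ss_subj / (n - 1)
  msc <- ss_col / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Davies-Bouldin by looping over all class pairs
oracle_dbi <- function(points, labels) {
  labs <- unique(labels)
  cent <- list()
  scat <- list()
  for (l in labs) {
    p <- points[labels == l, , drop = FALSE]
    cent[[l]] <- colMeans(p)
    d <- 0
    for (r in seq_len(nrow(p))) d <- d + sqrt(sum((p[r, ] - cent[[l]])^2))
    scat[[l]] <- d / nrow(p)
  }
  total <- 0
  for (l in labs) {
    worst <- -Inf
    for (m in setdiff(labs, l)) {
      sep <- sqrt(sum((cent[[l]] - cent[[m]])^2))
      worst <- max(worst, (scat[[l]] + scat[[m]]) / sep)
    }
    total <- total + worst
  }
  total / length(labs)
}

# mean silhouette, singleton contributes 1, per-point loops
oracle_silhouette <- function(points, labels) {
  n <- nrow(points)
  s <- numeric(n)
  for (i in 1:n) {
    own <- labels[i]
    mates <- which(labels == own & seq_len(n) != i)
    if (length(mates) == 0) {
      s[i] <- 1
      next
    }
    a <- 0
    for (j in mates) a <- a + sqrt(sum((points[i, ] - points[j, ])^2))
    a <- a / length(mates)
    b <- Inf
    for (cl in setdiff(unique(labels), own)) {
      members <- which(labels == cl)
      d <- 0
      for (j in members) d <- d + sqrt(sum((points[i, ] - points[j, ])^2))
      b <- min(b, d / length(members))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# KS statistic by sweeping the pooled sample points
oracle_ks <- function(x, y) {
  best <- 0
  for (t in c(x, y)) {
    d <- abs(mean(x <= t) - mean(y <= t))
    best <- max(best, d)
  }
  best
}

# tiny config for fast end-to-end tests
small_config <- function(participants_per_fst = rep(2L, 6),
                         lesion_range = c(2L, 3L),
                         crowd_users = 15L,
                         crowd_reads_per_image = 5L,
                         patch_size = 8L, ...) {
  study_config(participants_per_fst = participants_per_fst,
               lesion_range = lesion_range,
               crowd_users = crowd_users,
               crowd_reads_per_image = crowd_reads_per_image,
               patch_size = patch_size, ...)
}
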