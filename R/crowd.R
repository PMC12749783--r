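# Aggregation of crowdsourced ordinal labels: sequential qualification by
# trailing accuracy rank, and the 70%-of->=3 / plurality-beyond-12 majority
# rule. A crowd log is a data frame with one row per read:
# user_id, image_id, order, label, is_gold, gold_label.

#' Trailing average accuracy of one annotator
#'
#' At each scored read, the mean correctness over the last `window` scored
#' reads (all of them while fewer than `window` have accrued).
#'
#' @param correct Logical/0-1 vector of one user's scored reads, in order.
#' @param window Number of trailing reads averaged; default 50.
#' @return Numeric vector, same length as `correct`.
#' @export
trailing_accuracy <- function(correct, window = 50) {
  correct <- as.numeric(correct)
  if (length(correct) < 1) stop_tonescale("need >= 1 scored read", "too_few")
  n <- length(correct)
  cs <- cumsum(correct)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - window + 1L)
    (cs[i] - if (lo > 1L) cs[lo - 1L] else 0) / (i - lo + 1L)
  }, numeric(1))
}

#' Flag qualified reads by trailing-accuracy rank
#'
#' Processes the log in read order. Each user's trailing accuracy is updated
#' at every gold-scored read; a read is qualified iff, at that moment, its
#' user's trailing accuracy is at or above the cut keeping the top
#' `percentile` percent of users (the `100 - percentile` order-statistic
#' quantile of all users' current accuracies; ties rank equally). Users with
#' no scored history yet are not qualified.
#'
#' @param reads Crowd log data frame with columns `user_id`, `image_id`,
#'   `order`, `label`, `is_gold`, `gold_label`.
#' @param percentile Keep users in the top this-many percent; default 80.
#' @param window Trailing window passed to the accuracy bookkeeping.
#' @return `reads` with an added logical column `qualified`, in the original
#'   row order.
#' @export
qualify_reads <- function(reads, percentile = 80, window = 50) {
  need <- c("user_id", "image_id", "order", "label", "is_gold", "gold_label")
  stopifnot(all(need %in% names(reads)))
  if (length(unique(reads$user_id)) < 2) {
    stop_tonescale("qualification needs >= 2 users", "too_few_users")
  }
  ord <- order(reads$order)
  p_cut <- (100 - percentile) / 100
  acc_env <- new.env(parent = emptyenv())   # user -> correctness history
  cur <- new.env(parent = emptyenv())       # user -> current trailing accuracy
  qualified <- logical(nrow(reads))
  for (i in ord) {
    u <- as.character(reads$user_id[i])
    if (isTRUE(reads$is_gold[i])) {
      hist <- c(get0(u, envir = acc_env, ifnotfound = numeric(0)),
                as.numeric(reads$label[i] == reads$gold_label[i]))
      if (length(hist) > window) hist <- hist[(length(hist) - window + 1):length(hist)]
      assign(u, hist, envir = acc_env)
      assign(u, mean(hist), envir = cur)
    }
    accs <- unlist(as.list(cur))
    my <- get0(u, envir = cur, ifnotfound = NA_real_)
    if (length(accs) == 0 || is.na(my)) {
      qualified[i] <- FALSE
    } else {
      cut <- sort(accs)[max(1L, ceiling(p_cut * length(accs)))]
      qualified[i] <- my >= cut
    }
  }
  reads$qualified <- qualified
  reads
}

#' Majority label of one image from qualified reads
#'
#' With 12 or fewer qualified reads, a label is assigned iff there are at
#' least 3 reads and the most frequent label covers at least 70 percent of
#' them; with more than 12 reads the plurality label wins, ties remaining
#' unresolved.
#'
#' @param labels Vector of qualified-read labels for one image (may be
#'   empty).
#' @param min_reads Minimum qualified reads, default 3.
#' @param supermajority Required supporting fraction on the small-count
#'   branch, default 0.70.
#' @param plurality_above Read count beyond which plurality decides,
#'   default 12.
#' @return List with `label` (`NA` when unresolved), `n_reads`,
#'   `support` (top label's fraction, `NA` for empty input).
#' @export
majority_label <- function(labels, min_reads = 3, supermajority = 0.70,
                           plurality_above = 12) {
  labels <- labels[!is.na(labels)]
  n <- length(labels)
  if (n == 0) return(list(label = NA, n_reads = 0L, support = NA_real_))
  counts <- sort(table(labels), decreasing = TRUE)
  top_share <- counts[1] / n
  top_tied <- sum(counts == counts[1]) > 1
  lab <- NA
  if (n > plurality_above) {
    if (!top_tied) lab <- names(counts)[1]
  } else if (n >= min_reads && top_share >= supermajority && !top_tied) {
    lab <- names(counts)[1]
  }
  list(label = lab, n_reads = n, support = unname(top_share))
}

#' Aggregate a qualified crowd log to per-image majority labels
#'
#' @param reads Output of [qualify_reads()] (must carry `qualified`).
#' @inheritParams majority_label
#' @return Tibble with `image_id`, `label`, `n_reads`, `support`.
#' @export
aggregate_crowd <- function(reads, min_reads = 3, supermajority = 0.70,
                            plurality_above = 12) {
  stopifnot("qualified" %in% names(reads))
  q <- reads[reads$qualified, , drop = FALSE]
  ids <- sort(unique(reads$image_id))
  rows <- lapply(ids, function(img) {
    ml <- majority_label(q$label[q$image_id == img], min_reads,
                         supermajority, plurality_above)
    tibble::tibble(image_id = img,
                   label = if (is.na(ml$label)) NA_integer_
                           else as.integer(ml$label),
                   n_reads = ml$n_reads, support = ml$support)
  })
  dplyr::bind_rows(rows)
}

#' Compare crowd majority labels with an in-person reference
#'
#' Builds the reference-by-crowd concordance table over images with a
#' resolved majority label and a reference label, and computes the
#' linear-weighted kappa and per-class concordance. Unresolved images are
#' excluded.
#'
#' @param majority Tibble from [aggregate_crowd()].
#' @param reference Data frame with columns `image_id` and `reference`
#'   (class in `1..k`).
#' @param k Scale size, default 6 (FST).
#' @return List with `table` (k x k), `kappa`, `concordance`
#'   (from [concordance_by_class()]), `n`.
#' @export
crowd_vs_reference <- function(majority, reference, k = 6) {
  m <- merge(majority, reference, by = "image_id")
  m <- m[!is.na(m$label) & !is.na(m$reference), , drop = FALSE]
  if (nrow(m) < 2) stop_tonescale("need >= 2 resolved labeled images", "too_few")
  tab <- table(factor(m$reference, levels = 1:k),
               factor(m$label, levels = 1:k))
  list(table = unclass(tab),
       kappa = linear_weighted_kappa(m$reference, m$label, k),
       concordance = concordance_by_class(tab),
       n = nrow(m))
}
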