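# How tightly do a subjective scale's categories cluster in objective
# colorimeter (L*, b*) space? Clusters are label-defined (no fitting): we
# report per-class centroids and radii, the Davies-Bouldin index, and the
# mean silhouette with the singleton-equals-one convention.

#' Select one rating per site at random
#'
#' Where both raters provided a rating, picks one uniformly at random
#' (seeded, reproducible); where only one rated, that rating is used. The
#' caller's RNG state is left untouched.
#'
#' @param rating_1,rating_2 Rating vectors of equal length; `NA` marks a
#'   missing rating.
#' @param seed Integer seed controlling the rater choice.
#' @return Vector of selected ratings (`NA` where neither rater rated).
#' @export
select_single_rating <- function(rating_1, rating_2, seed) {
  stopifnot(length(rating_1) == length(rating_2))
  n <- length(rating_1)
  pick_first <- with_seed(seed, stats::runif(n) < 0.5)
  out <- ifelse(is.na(rating_1), rating_2,
                ifelse(is.na(rating_2), rating_1,
                       ifelse(pick_first, rating_1, rating_2)))
  out
}

#' Per-class centroids and radii in (L, b) space
#'
#' Centroid is the arithmetic mean; the radius is the population standard
#' deviation of members' Euclidean distances to their centroid (the circle
#' geometry of a cluster-dispersion scatter plot). Singleton classes have
#' radius 0.
#'
#' @param points Numeric `n x 2` matrix (columns L, b) or data frame.
#' @param labels Class label per point.
#' @return Tibble with `label`, `centroid_L`, `centroid_b`, `radius`, `n`.
#' @export
class_centroids <- function(points, labels) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) == length(labels))
  split_idx <- split(seq_len(nrow(points)), labels)
  rows <- lapply(names(split_idx), function(lab) {
    p <- points[split_idx[[lab]], , drop = FALSE]
    cen <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, cen)^2))
    tibble::tibble(label = lab, centroid_L = cen[1], centroid_b = cen[2],
                   radius = sqrt(mean((d - mean(d))^2)), n = nrow(p))
  })
  dplyr::bind_rows(rows)
}

# Mean Euclidean distance of each class's members to its centroid (the
# Davies-Bouldin scatter), plus the centroid matrix.
.db_scatter <- function(points, labels) {
  split_idx <- split(seq_len(nrow(points)), labels)
  cent <- t(vapply(split_idx, function(i) colMeans(points[i, , drop = FALSE]),
                   numeric(ncol(points))))
  s <- vapply(seq_along(split_idx), function(j) {
    p <- points[split_idx[[j]], , drop = FALSE]
    mean(sqrt(rowSums(sweep(p, 2, cent[j, ])^2)))
  }, numeric(1))
  list(centroids = cent, scatter = s, labels = names(split_idx))
}

#' Davies-Bouldin index of a labeled point set
#'
#' `DBI = mean_i max_{j != i} (S_i + S_j) / M_ij` with `S` the mean
#' Euclidean distance of class members to their centroid and `M` the
#' Euclidean distance between centroids. Lower values indicate tighter,
#' better-separated classes.
#'
#' @param points Numeric matrix (rows = observations).
#' @param labels Class label per point; at least 2 distinct classes.
#' @return DBI, a nonnegative scalar.
#' @export
davies_bouldin <- function(points, labels) {
  points <- as.matrix(points)
  stopifnot(nrow(points) == length(labels))
  if (length(unique(labels)) < 2) {
    stop_tonescale("need >= 2 distinct classes", "too_few_classes")
  }
  sc <- .db_scatter(points, labels)
  k <- length(sc$scatter)
  M <- as.matrix(stats::dist(sc$centroids))
  off <- M[upper.tri(M)]
  if (any(off == 0)) {
    stop_tonescale("two class centroids coincide; DBI undefined",
                   "coincident_centroids")
  }
  r <- vapply(seq_len(k), function(i) {
    max((sc$scatter[i] + sc$scatter[-i]) / M[i, -i])
  }, numeric(1))
  mean(r)
}

#' Mean silhouette width with the singleton convention
#'
#' For each point, `s = (b - a) / max(a, b)` where `a` is the mean distance
#' to its own class's other members and `b` the smallest mean distance to
#' any other class. A point that is its class's only member contributes
#' exactly 1. Returns the mean over all points (the Rousseeuw silhouette
#' index of the labeling).
#'
#' @inheritParams davies_bouldin
#' @return Mean silhouette in `[-1, 1]`.
#' @export
silhouette_mean <- function(points, labels) {
  points <- as.matrix(points)
  stopifnot(nrow(points) == length(labels))
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    stop_tonescale("need >= 2 distinct classes", "too_few_classes")
  }
  D <- as.matrix(stats::dist(points))
  n <- nrow(points)
  sizes <- table(labels)
  s <- vapply(seq_len(n), function(i) {
    own <- labels[i]
    if (sizes[[own]] == 1L) return(1)
    a <- mean(D[i, labels == own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), own),
                    function(cl) mean(D[i, labels == cl]), numeric(1)))
    if (max(a, b) == 0) return(0)
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Dispersion report for one labeling scheme
#'
#' Bundles [class_centroids()], [davies_bouldin()] and [silhouette_mean()]
#' for one scale's labels on a common (L, b) point set.
#'
#' @inheritParams davies_bouldin
#' @param scale Name of the labeling scheme (for printing).
#' @return Object of class `dispersion_report`: a list with `scale`,
#'   `classes` (tibble), `dbi`, `rsi`, `n`.
#' @export
dispersion_report <- function(points, labels, scale = "scale") {
  points <- as.matrix(points)
  rep <- list(scale = scale,
              classes = class_centroids(points, labels),
              dbi = davies_bouldin(points, labels),
              rsi = silhouette_mean(points, labels),
              n = nrow(points))
  structure(rep, class = "dispersion_report")
}

#' @export
print.dispersion_report <- function(x, ...) {
  cat(sprintf("<dispersion_report> %s: %d points, %d classes\n",
              x$scale, x$n, nrow(x$classes)))
  cat(sprintf("  DBI %.3f  RSI %.3f\n", x$dbi, x$rsi))
  invisible(x)
}

#' Compare dispersion of several labeling schemes on identical points
#'
#' Computes one [dispersion_report()] per scale on the same point set, and
#' optionally a per-anatomic-site stratification. Scales with a single
#' represented class are reported as `NULL` with a warning.
#'
#' @param points Numeric `n x 2` matrix of (L, b) coordinates.
#' @param label_sets Named list of label vectors (e.g. `fst`, `mst`,
#'   `pantone`), each of length `nrow(points)`.
#' @param sites Optional anatomic-site vector for stratified reports.
#' @return Named list of `dispersion_report`s; if `sites` is given, an
#'   additional attribute `by_site` holds a scale x site list.
#' @export
dispersion_compare <- function(points, label_sets, sites = NULL) {
  points <- as.matrix(points)
  one <- function(labels, nm) {
    if (length(unique(labels[!is.na(labels)])) < 2) {
      warn_tonescale(sprintf("scale '%s' has < 2 classes; skipped", nm),
                     "too_few_classes")
      return(NULL)
    }
    keep <- !is.na(labels)
    dispersion_report(points[keep, , drop = FALSE], labels[keep], scale = nm)
  }
  reports <- lapply(names(label_sets), function(nm) one(label_sets[[nm]], nm))
  names(reports) <- names(label_sets)
  if (!is.null(sites)) {
    by_site <- lapply(names(label_sets), function(nm) {
      labs <- label_sets[[nm]]
      lapply(split(seq_along(sites), sites), function(idx) {
        if (length(unique(labs[idx][!is.na(labs[idx])])) < 2 ||
            length(idx) < 3) return(NULL)
        keep <- idx[!is.na(labs[idx])]
        tryCatch(
          dispersion_report(points[keep, , drop = FALSE], labs[keep], nm),
          tonescale_error = function(e) NULL)
      })
    })
    names(by_site) <- names(label_sets)
    attr(reports, "by_site") <- by_site
  }
  reports
}

#' Scatter plot of a dispersion analysis
#'
#' Points in (L, b) space colored by class, with centroid circles whose
#' radii are the per-class SD of intra-cluster distances.
#'
#' @param report A [dispersion_report()].
#' @param points,labels The point set and labels the report was built from.
#' @return A ggplot object.
#' @export
plot_dispersion <- function(report, points, labels) {
  points <- as.matrix(points)
  df <- tibble::tibble(L = points[, 1], b = points[, 2],
                       class = as.character(labels))
  cl <- report$classes
  ang <- seq(0, 2 * pi, length.out = 90)
  circles <- dplyr::bind_rows(lapply(seq_len(nrow(cl)), function(i) {
    tibble::tibble(class = cl$label[i],
                   L = cl$centroid_L[i] + cl$radius[i] * cos(ang),
                   b = cl$centroid_b[i] + cl$radius[i] * sin(ang))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$b, y = .data$L,
                                   color = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_path(data = circles,
                       ggplot2::aes(group = .data$class), linewidth = 0.4) +
    ggplot2::labs(title = sprintf("%s: DBI %.2f, RSI %.2f",
                                  report$scale, report$dbi, report$rsi),
                  x = "b* (yellow chromaticity)", y = "L* (luminance)") +
    ggplot2::theme_minimal()
}
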