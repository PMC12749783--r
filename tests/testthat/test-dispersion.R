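test_that("random rater selection is seeded, unbiased and handles missing", {
  expect_equal(select_single_rating(c(3, NA), c(NA, 5), seed = 1), c(3, 5))
  r1 <- rep(1, 1e4)
  r2 <- rep(2, 1e4)
  pick_a <- select_single_rating(r1, r2, seed = 99)
  pick_b <- select_single_rating(r1, r2, seed = 99)
  expect_identical(pick_a, pick_b)
  expect_equal(mean(pick_a == 1), 0.5, tolerance = 0.02)
})

test_that("class centroids and SD-radii match the circle geometry", {
  one <- class_centroids(matrix(c(3, 4), 1), "x")
  expect_equal(one$centroid_L, 3)
  expect_equal(one$radius, 0)
  sym <- class_centroids(rbind(c(-1, -2), c(1, 2)), c("x", "x"))
  expect_equal(sym$centroid_L, 0)
  expect_equal(sym$centroid_b, 0)
  expect_equal(sym$radius, 0)  # equal distances: SD is zero
  sq <- class_centroids(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)), rep("s", 4))
  expect_equal(sq$centroid_L, 0.5)
  expect_equal(sq$radius, 0)
})

test_that("Davies-Bouldin hits hand-computed anchors", {
  # two singleton classes: zero scatter
  expect_equal(davies_bouldin(rbind(c(0, 0), c(5, 0)), c("a", "b")), 0)
  # two 2-point classes with scatter 1 each, centroids 4 apart: (1+1)/4
  pts <- rbind(c(-1, 0), c(1, 0), c(3, 0), c(5, 0))
  expect_equal(davies_bouldin(pts, c("a", "a", "b", "b")), 0.5)
  expect_error(davies_bouldin(rbind(c(0, 0), c(1, 1)), c("a", "a")),
               class = "tonescale_too_few_classes")
  expect_error(davies_bouldin(rbind(c(0, 0), c(0, 0), c(1, 0), c(-1, 0)),
                              c("a", "a", "b", "b")),
               class = "tonescale_coincident_centroids")
})

test_that("DBI and silhouette match brute-force oracles on random instances", {
  set.seed(202)
  for (i in 1:30) {
    n <- sample(6:12, 1)
    k <- sample(2:4, 1)
    pts <- matrix(rnorm(2 * n), ncol = 2)
    labs <- as.character(sample(1:k, n, replace = TRUE))
    if (length(unique(labs)) < 2) next
    expect_equal(davies_bouldin(pts, labs), oracle_dbi(pts, labs),
                 tolerance = 1e-12)
    expect_equal(silhouette_mean(pts, labs), oracle_silhouette(pts, labs),
                 tolerance = 1e-12)
  }
})

test_that("silhouette matches cluster::silhouette when no singletons exist", {
  skip_if_not_installed("cluster")
  set.seed(31)
  pts <- matrix(rnorm(60), ncol = 2)
  labs <- rep(1:3, each = 10)
  ref <- mean(cluster::silhouette(labs, stats::dist(pts))[, "sil_width"])
  expect_equal(silhouette_mean(pts, labs), ref, tolerance = 1e-10)
})

test_that("silhouette conventions: separation, randomness, singletons", {
  tight <- rbind(c(0, 0), c(0, 0.01), c(10, 10), c(10, 10.01))
  expect_gt(silhouette_mean(tight, c("a", "a", "b", "b")), 0.9)
  set.seed(44)
  blob <- matrix(rnorm(1000), ncol = 2)
  labs <- sample(c("x", "y"), 500, replace = TRUE)
  expect_lt(abs(silhouette_mean(blob, labs)), 0.05)
  # a singleton's contribution is exactly 1: hand-computed mean for
  # points (0,0),(0,1) in one class and a lone point at (5,5)
  pts <- rbind(c(0, 0), c(0, 1), c(5, 5))
  s1 <- (sqrt(50) - 1) / sqrt(50)
  s2 <- (sqrt(41) - 1) / sqrt(41)
  expect_equal(silhouette_mean(pts, c("a", "a", "lone")),
               (s1 + s2 + 1) / 3, tolerance = 1e-12)
})

test_that("dispersion indices are rigid-motion invariant and scatter-monotone", {
  set.seed(55)
  pts <- matrix(rnorm(80, sd = 2), ncol = 2)
  labs <- rep(1:4, each = 10)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  moved <- pts %*% R + matrix(c(30, -12), 40, 2, byrow = TRUE)
  expect_equal(davies_bouldin(moved, labs), davies_bouldin(pts, labs),
               tolerance = 1e-10)
  expect_equal(silhouette_mean(moved, labs), silhouette_mean(pts, labs),
               tolerance = 1e-10)

  # shrinking classes toward their centroids tightens both indices
  shrink <- function(p, l, t) {
    out <- p
    for (cl in unique(l)) {
      idx <- l == cl
      cen <- colMeans(p[idx, , drop = FALSE])
      out[idx, ] <- sweep(sweep(p[idx, , drop = FALSE], 2, cen), 1:2,
                          t, "*")
      out[idx, ] <- sweep(out[idx, , drop = FALSE], 2, cen, "+")
    }
    out
  }
  tightened <- shrink(pts, labs, 0.5)
  expect_lt(davies_bouldin(tightened, labs), davies_bouldin(pts, labs))
  expect_gt(silhouette_mean(tightened, labs), silhouette_mean(pts, labs))

  # DBI decreases monotonically over a within-class SD grid
  centers <- matrix(c(0, 0, 10, 0, 0, 10, 10, 10, 5, 5), ncol = 2, byrow = TRUE)
  dbis <- vapply(c(4, 3, 2, 1, 0.5), function(s) {
    set.seed(60)
    p <- centers[rep(1:5, each = 30), ] + matrix(rnorm(300, sd = s), ncol = 2)
    davies_bouldin(p, rep(1:5, each = 30))
  }, numeric(1))
  expect_true(all(diff(dbis) < 0))
})

test_that("dispersion_compare runs scales on identical points", {
  set.seed(66)
  pts <- matrix(rnorm(60, 50, 10), ncol = 2)
  labs <- as.character(rep(1:3, each = 10))
  res <- dispersion_compare(pts, list(s1 = labs, s2 = labs))
  expect_equal(res$s1$dbi, res$s2$dbi)
  expect_equal(res$s1$rsi, res$s2$rsi)
  expect_warning(
    res2 <- dispersion_compare(pts, list(only = rep("x", 30))),
    class = "tonescale_too_few_classes")
  expect_null(res2$only)
})
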