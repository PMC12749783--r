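test_that("weighted kappa is 1 for perfect agreement and ~0 under shuffling", {
  a <- rep(1:5, each = 4)
  expect_equal(linear_weighted_kappa(a, a, k = 5), 1)
  set.seed(101)
  x <- sample(1:6, 5000, replace = TRUE)
  y <- sample(x)  # same marginals, no association
  expect_lt(abs(linear_weighted_kappa(x, y, k = 6)), 0.05)
})

test_that("weighted kappa matches the cell-enumeration oracle", {
  # the 3x3 example: counts [[4,1,0],[1,4,1],[0,1,4]]
  a <- c(rep(1, 5), rep(2, 6), rep(3, 5))
  b <- c(rep(1, 4), 2, 1, rep(2, 4), 3, 2, rep(3, 4))
  expect_equal(linear_weighted_kappa(a, b, k = 3), oracle_kappa(a, b, 3),
               tolerance = 1e-12)
  set.seed(42)
  for (i in 1:30) {
    k <- sample(3:8, 1)
    n <- sample(5:12, 1)
    x <- sample(1:k, n, replace = TRUE)
    y <- sample(1:k, n, replace = TRUE)
    if (length(unique(c(x, y))) == 1) next
    expect_equal(linear_weighted_kappa(x, y, k), oracle_kappa(x, y, k),
                 tolerance = 1e-12)
  }
})

test_that("kappa symmetries: rater swap and order-preserving relabel", {
  set.seed(5)
  x <- sample(1:5, 60, replace = TRUE)
  y <- pmin(pmax(x + sample(-1:1, 60, replace = TRUE), 1), 5)
  k0 <- linear_weighted_kappa(x, y, k = 7)
  expect_equal(linear_weighted_kappa(y, x, k = 7), k0)
  expect_equal(linear_weighted_kappa(x + 2, y + 2, k = 7), k0)
})

test_that("kappa is flagged undefined when both raters are constant", {
  expect_warning(res <- linear_weighted_kappa(rep(2, 10), rep(2, 10), k = 4),
                 class = "tonescale_degenerate_marginals")
  expect_true(is.na(res))
})

test_that("ICC(2,1) hits its anchors and the ANOVA oracle", {
  m <- matrix(rep(c(1, 5, 9, 13), 3), ncol = 3)
  expect_equal(icc_agreement(m), 1)
  set.seed(8)
  iid <- matrix(rnorm(2000 * 2), ncol = 2)
  expect_lt(abs(icc_agreement(iid)), 0.05)
  set.seed(9)
  subj <- rnorm(4, 0, 2)
  m2 <- outer(subj, rep(1, 3)) + matrix(rnorm(12), 4, 3)
  expect_equal(icc_agreement(m2), oracle_icc(m2), tolerance = 1e-10)
  expect_error(icc_agreement(matrix(rep(c(1, 2, 3), 4), nrow = 4, byrow = TRUE)),
               class = "tonescale_zero_variance")
})

test_that("ICC estimates recover the generating variance ratio", {
  set.seed(77)
  sigma_s <- 2
  sigma_e <- 1
  n <- 2000
  m <- outer(rnorm(n, 0, sigma_s), rep(1, 3)) + matrix(rnorm(3 * n, 0, sigma_e), n, 3)
  expect_equal(icc_agreement(m), sigma_s^2 / (sigma_s^2 + sigma_e^2),
               tolerance = 0.05)
})

test_that("paired mean difference: identity, degenerate shift, closed form", {
  x <- c(1, 2, 3, 4, 5)
  res <- paired_mean_difference(x, x)
  expect_equal(res$mean_difference, 0)
  expect_equal(res$p_value, 1)
  expect_error(paired_mean_difference(x, x + 1),
               class = "tonescale_zero_variance_differences")
  set.seed(2)
  a <- rnorm(10)
  b <- a + rnorm(10, 0.5)
  d <- b - a
  res2 <- paired_mean_difference(a, b)
  expect_equal(res2$t, mean(d) / (sd(d) / sqrt(10)), tolerance = 1e-12)
  expect_equal(res2$mean_difference, mean(d))
})

test_that("chi-squared independence: anchors, dof, invariance, errors", {
  indep <- outer(c(10, 20), c(5, 15)) / 50
  expect_equal(chi_squared_independence(indep)$statistic, 0, tolerance = 1e-12)
  res <- chi_squared_independence(matrix(c(10, 0, 0, 10), 2))
  expect_equal(res$statistic, 20)
  expect_equal(chi_squared_independence(matrix(1, 6, 4))$dof, 15)
  set.seed(3)
  tab <- matrix(rpois(12, 8) + 1, 3, 4)
  s0 <- chi_squared_independence(tab)$statistic
  expect_equal(chi_squared_independence(tab[c(2, 3, 1), c(4, 1, 3, 2)])$statistic,
               s0, tolerance = 1e-12)
  expect_error(chi_squared_independence(matrix(c(1, 0, 2, 0), 2)),
               class = "tonescale_zero_expected")
})

test_that("concordance by class: identity, partial rows, empty rows", {
  expect_equal(concordance_by_class(diag(5) * 3)$overall, 100)
  expect_true(all(concordance_by_class(diag(5) * 3)$per_class == 100))
  tab <- matrix(c(5, 15, 0, 0, 4, 1, 0, 1, 4), 3, byrow = TRUE)
  res <- concordance_by_class(tab)
  expect_equal(unname(res$per_class[1]), 25)
  tab2 <- matrix(c(4, 1, 1, 4), 2, byrow = TRUE)
  expect_equal(concordance_by_class(tab2)$overall, 80)
  tab3 <- rbind(c(2, 1, 0), c(0, 0, 0), c(0, 0, 3))
  expect_true(is.na(concordance_by_class(tab3)$per_class[2]))
})

test_that("per-site agreement pools correctly and recovers noise ordering", {
  d <- tibble::tibble(
    rating_a = c(1, 2, 3, 1, 4, 5, 2, 3),
    rating_b = c(1, 2, 3, 1, 4, 5, 2, 3),
    anatomic_site = rep(c("abdomen", "calf"), each = 4),
    lesional = FALSE)
  tab <- agreement_by_site(d, k = 6)
  expect_true(all(tab$kappa[tab$stratum %in% c("abdomen", "calf")] == 1))

  # the all-sites row is the pooled statistic, not the mean of per-site rows
  set.seed(12)
  d2 <- tibble::tibble(
    rating_a = sample(1:6, 80, replace = TRUE),
    anatomic_site = rep(c("a", "b"), each = 40),
    lesional = FALSE)
  d2$rating_b <- pmin(pmax(d2$rating_a + sample(-1:1, 80, replace = TRUE), 1), 6)
  tab2 <- agreement_by_site(d2, k = 6)
  pooled <- linear_weighted_kappa(d2$rating_a, d2$rating_b, 6)
  expect_equal(tab2$kappa[tab2$stratum == "all_sites"], pooled)
  per_site_mean <- mean(tab2$kappa[tab2$stratum %in% c("a", "b")])
  expect_false(isTRUE(all.equal(pooled, per_site_mean, tolerance = 1e-10)))

  # site-dependent rater noise: noisier site gets the lower kappa
  truth <- sample(1:10, 400, replace = TRUE)
  quiet <- rate_with_noise(truth, c(0.9, 0.05, 0), 10, seed = 21)
  noisy <- rate_with_noise(truth, c(0.3, 0.2, 0.15), 10, seed = 22)
  d3 <- tibble::tibble(
    rating_a = rep(truth, 2),
    rating_b = c(quiet, noisy),
    anatomic_site = rep(c("forearm", "sole"), each = 400),
    lesional = FALSE)
  tab3 <- agreement_by_site(d3, k = 10)
  expect_gt(tab3$kappa[tab3$stratum == "forearm"],
            tab3$kappa[tab3$stratum == "sole"])
})
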