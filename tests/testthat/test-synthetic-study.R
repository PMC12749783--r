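test_that("config validation rejects malformed settings", {
  expect_error(study_config(mst_kernel = c(0.5, 0.5, 0.5)),
               class = "tonescale_config")
  expect_error(study_config(mst_L = rep(50, 10)), class = "tonescale_config")
  expect_error(study_config(participants_per_fst = c(1, 2)),
               class = "tonescale_config")
  expect_error(study_config(colorimeter_fraction = 1.5),
               class = "tonescale_config")
  expect_error(study_config(score_mean = rep(0.5, 9)),
               class = "tonescale_config")
})

test_that("generated study matches the configured bookkeeping", {
  cfg <- study_config()
  st <- generate_study(cfg, include_images = FALSE)
  expect_equal(nrow(st$participants), 64)
  expect_equal(as.numeric(table(st$participants$fst)),
               c(10, 12, 11, 10, 11, 10))
  n_sites <- nrow(st$sites)
  expect_gte(n_sites, 64 * (5 + 11))
  expect_lte(n_sites, 64 * (13 + 11))
  expect_equal(sum(st$sites$site_kind == "nonlesional"), 64 * 11)
  expect_true(all(st$sites$fst %in% 1:6))
  expect_true(all(st$sites$mst_r1 %in% 1:10 & st$sites$mst_r2 %in% 1:10))
  # colorimeter coverage: configured fraction of participants, non-lesional only
  expect_equal(sum(st$participants$colorimeter), round(0.734 * 64))
  expect_true(all(is.na(st$sites$col_L1[st$sites$site_kind == "lesional"])))
  # mean true L* strictly decreases across MST shades
  mu <- tapply(st$sites$true_L, st$sites$true_mst, mean)
  expect_true(all(diff(mu) < 0))
})

test_that("generation is deterministic in the master seed", {
  cfg <- small_config(seed = 77L)
  a <- generate_study(cfg)
  b <- generate_study(cfg)
  expect_identical(a$sites, b$sites)
  expect_identical(a$crowd, b$crowd)
  expect_identical(a$scores, b$scores)
  expect_identical(a$images[[1]]$pixels, b$images[[1]]$pixels)
  c <- generate_study(small_config(seed = 78L), include_images = FALSE)
  expect_false(identical(a$sites$mst_r1, c$sites$mst_r1))
})

test_that("true site colors echo the configured means, offsets and SDs", {
  cfg <- study_config(participant_sd_L = 0, participant_sd_b = 0,
                      site_noise_L = 0, site_noise_b = 0)
  col <- true_site_color(cfg, mst = c(1, 1, 5), site = c("forearm", "sole", "abdomen"))
  expect_equal(unname(col[1, "L"]), cfg$mst_L[1] + cfg$site_offset_L[["forearm"]])
  expect_equal(unname(col[2, "L"]), cfg$mst_L[1] + cfg$site_offset_L[["sole"]])
  expect_gt(col[2, "L"], col[1, "L"])  # callused sun-protected site lighter
  expect_equal(unname(col[3, "b"]), cfg$mst_b[5])

  cfg2 <- study_config(site_noise_L = 3)
  draws <- true_site_color(cfg2, rep(5, 1e4), rep("abdomen", 1e4), seed = 5)
  expect_equal(sd(draws[, "L"]), 3, tolerance = 0.05 * 3)
})

test_that("ordinal rater noise kernel behaves as configured", {
  truth <- sample(1:10, 200, replace = TRUE)
  expect_equal(rate_with_noise(truth, c(1, 0, 0), 10, seed = 1), truth)
  # exact-agreement rate of two independent raters is the kernel self-convolution
  kern <- c(0.7, 0.15, 0)
  t2 <- rep(5L, 1e5)  # interior class: no clipping
  r1 <- rate_with_noise(t2, kern, 10, seed = 21)
  r2 <- rate_with_noise(t2, kern, 10, seed = 22)
  expect_equal(mean(r1 == r2), 0.7^2 + 2 * 0.15^2, tolerance = 0.01)
  # clipping keeps ratings in range at the scale ends
  ends <- rate_with_noise(rep(c(1L, 10L), 500), c(0.2, 0.2, 0.2), 10, seed = 3)
  expect_true(all(ends >= 1 & ends <= 10))
})

test_that("implied kappa matches a large-sample empirical kappa", {
  kern <- c(0.5, 0.2, 0.05)
  p <- c(0.05, 0.1, 0.1, 0.15, 0.15, 0.15, 0.1, 0.1, 0.05, 0.05)
  truth <- sample(1:10, 4e4, replace = TRUE, prob = p)
  r1 <- rate_with_noise(truth, kern, 10, seed = 31)
  r2 <- rate_with_noise(truth, kern, 10, seed = 32)
  emp <- linear_weighted_kappa(r1, r2, 10)
  p_emp <- as.numeric(table(factor(truth, levels = 1:10)) / length(truth))
  expect_equal(implied_kappa(p_emp, kern, 10), emp, tolerance = 0.02)
})

test_that("rendered patches carry the configured color and mode shifts", {
  lab <- c(55, 11, 16)
  clean <- render_patch(lab, size = 8, noise_sd = 0)
  expect_equal(image_ita(clean), ita_from_lab(lab), tolerance = 1.5)
  shifted <- render_patch(lab, mode_offset = c(8, 0), size = 8, noise_sd = 0)
  L_shift <- rgb_to_lab(median_rgb(shifted))[1, "L"] -
    rgb_to_lab(median_rgb(clean))[1, "L"]
  expect_equal(L_shift, 8, tolerance = 1)
  # polarized vs non-polarized b* offsets separate the extracted chroma
  pol <- render_patch(lab, mode_offset = c(0, 2.5), size = 8, noise_sd = 0)
  nonpol <- render_patch(lab, mode_offset = c(0, -2.5), size = 8, noise_sd = 0)
  expect_gt(rgb_to_lab(median_rgb(pol))[1, "b"],
            rgb_to_lab(median_rgb(nonpol))[1, "b"])
  # noisy render still recovers the base color via the median
  noisy <- render_patch(lab, size = 16, noise_sd = 4, seed = 9)
  expect_equal(image_ita(noisy), ita_from_lab(lab), tolerance = 3)
})

test_that("score model is class-conditional Beta on the percent scale", {
  cfg <- study_config()
  s <- simulate_scores(cfg, rep(1:10, each = 400), seed = 17)
  expect_true(all(s >= 0 & s <= 100))
  mu <- tapply(s, rep(1:10, each = 400), mean)
  expect_gt(mean(mu[8:9]), mean(mu[1:7]))  # darkest-rated shades shifted up
  # near-degenerate Beta concentrates at its mean
  cfg2 <- study_config(score_concentration = 1e6)
  s2 <- simulate_scores(cfg2, rep(4L, 100), seed = 2)
  expect_equal(sd(s2), 0, tolerance = 0.05)
  expect_equal(mean(s2), 100 * cfg2$score_mean[4], tolerance = 0.1)
})

test_that("pantone codes round-trip and reject malformed input", {
  codes <- pantone_code(c(1, 8, 15), c(1, 6, 10))
  expect_equal(codes, c("5R01", "1Y08", "5Y15"))
  parsed <- parse_pantone(codes)
  expect_equal(parsed$pigment, c(1L, 8L, 15L))
  expect_equal(parsed$undertone, c(1L, 6L, 10L))
  expect_error(parse_pantone("XX07"), class = "tonescale_invalid_pantone")
})
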