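# Seeded generator for a full synthetic skin-tone study: an FST-balanced
# cohort, per-site true CIELAB colors on a monotone MST luminance ladder,
# two in-person raters with ordinal noise, colorimeter triplicates,
# lighting-biased TBP re-ratings, dermoscopy-style patches, a crowd log
# with heterogeneous annotator skill, and class-dependent classifier
# scores. Every stochastic step draws from a named substream of the master
# seed. Color parameters are configuration, not claims about real skin.

.nonlesional_sites <- c("forehead", "chest", "abdomen", "inner_upper_arm",
                        "inner_wrist", "forearm", "upper_back", "lower_back",
                        "shin", "calf", "sole")

.undertone_levels <- c("5R", "4R", "3R", "2R", "1R", "1Y", "2Y", "3Y", "4Y", "5Y")

.dermoscopy_modes <- c("P_C", "P_NC", "NP_C", "NP_NC")

#' Pantone-style swatch codes
#'
#' A swatch code combines an undertone level (ordered `5R..1R, 1Y..5Y`,
#' indices 1-10) with a pigment level (1 lightest - 15 darkest), e.g.
#' `"3Y08"`. `parse_pantone()` inverts the encoding.
#'
#' @param pigment Integer 1-15.
#' @param undertone Integer 1-10 (1 = `5R`, 10 = `5Y`).
#' @return `pantone_code()`: character codes; `parse_pantone()`: a list with
#'   integer vectors `pigment` and `undertone`.
#' @export
pantone_code <- function(pigment, undertone) {
  stopifnot(all(pigment %in% 1:15), all(undertone %in% 1:10))
  paste0(.undertone_levels[undertone], sprintf("%02d", pigment))
}

#' @rdname pantone_code
#' @param code Character swatch codes as produced by `pantone_code()`.
#' @export
parse_pantone <- function(code) {
  und <- match(substr(code, 1, 2), .undertone_levels)
  pig <- as.integer(substr(code, 3, 4))
  if (any(is.na(und) | is.na(pig) | pig < 1 | pig > 15)) {
    stop_tonescale("malformed Pantone-style code", "invalid_pantone")
  }
  list(pigment = pig, undertone = und)
}

#' Synthetic study configuration
#'
#' Defaults emulate a skin-tone-balanced prospective cohort: 64
#' participants spread nearly evenly over FST I-VI, 5-13 lesions plus 11
#' standardized non-lesional sites each, a monotone MST luminance ladder
#' with class-conditional noise, two in-person raters with ordinal error
#' kernels, colorimeter triplicates on a subset of participants, lighting
#' -mode biases for photography-based re-rating, a crowd with
#' heterogeneous skill, and class-dependent Beta score distributions with
#' the darkest rated shades shifted upward.
#'
#' An ordinal noise kernel is a length-3 vector `(exact, pm1, pm2)`: the
#' probability of rating the true class, each neighbor, and each
#' two-step neighbor (`exact + 2 pm1 + 2 pm2 = 1`); draws landing outside
#' the scale are clipped to its ends.
#'
#' @param participants_per_fst Integer vector of cohort sizes for FST I-VI.
#' @param lesion_range Min/max lesions per participant.
#' @param mst_L,mst_b True mean `L*`/`b*` per MST shade 1-10 (`mst_L` must be
#'   strictly decreasing).
#' @param participant_sd_L,participant_sd_b SD of participant deviation from
#'   the class mean.
#' @param site_noise_L,site_noise_b SD of site-level color noise.
#' @param site_offset_L Named numeric: systematic `L*` offset per
#'   non-lesional site (callused sun-protected sites lighter, exposed sites
#'   darker).
#' @param mst_kernel,pigment_kernel,undertone_kernel Rater noise kernels.
#' @param fst_given_mst_sd SD of the noisy MST-to-FST assignment (drives
#'   FST's wider conditional color variance).
#' @param colorimeter_fraction Fraction of participants measured with the
#'   colorimeter.
#' @param colorimeter_sd Triplicate measurement SD per Lab channel
#'   (length 3).
#' @param tbp_bias_wl,tbp_bias_xp,tbp_sd Lighting-mode rating bias (MST
#'   units; white light biases lighter i.e. negative, cross-polarized
#'   slightly darker i.e. positive) and rating noise SD.
#' @param mode_offset_L,mode_offset_b Named per-dermoscopy-mode Lab shifts
#'   applied when rendering patches.
#' @param device_jitter_L,device_jitter_b Per-image color-processing jitter
#'   SD (what makes image-extracted ITA agree poorly with colorimetry).
#' @param device_L_compression Luminance compression factor of the imaging
#'   chain: rendered `L*` is `55 + c (L* - 55)` before offsets and jitter,
#'   emulating flash illumination and auto-exposure flattening apparent
#'   brightness.
#' @param patch_size Rendered patch side length in pixels.
#' @param patch_noise_sd Per-pixel Gaussian RGB noise SD.
#' @param crowd_users,crowd_reads_per_image,crowd_gold_rate,crowd_skill
#'   Crowd size, reads per image, fraction of images scored against the
#'   in-person label, and the `(shape1, shape2)` of the Beta skill
#'   distribution (probability of an exact read).
#' @param crowd_image_sd SD of the shared per-image perception shift:
#'   every reader of an image sees the same lighting/site-distorted
#'   apparent FST, `clip(round(fst + N(0, crowd_image_sd)))`. This caps
#'   crowd-vs-in-person concordance no matter how skilled the crowd is.
#' @param score_mean Per-MST-shade mean of the Beta score model (0-1
#'   scale); defaults rise gently then jump for shades 8-9.
#' @param score_concentration Beta concentration (`shape1 + shape2`).
#' @param seed Master seed; all substreams derive from it.
#' @return A `study_config` list, validated.
#' @export
study_config <- function(
    participants_per_fst = c(10L, 12L, 11L, 10L, 11L, 10L),
    lesion_range = c(5L, 13L),
    mst_L = seq(75, 30, length.out = 10),
    mst_b = c(14, 15, 16, 17, 18, 18, 17, 16, 14, 12),
    participant_sd_L = 2.2,
    participant_sd_b = 1.2,
    site_noise_L = 1.4,
    site_noise_b = 0.9,
    site_offset_L = c(forehead = -2, chest = 1, abdomen = 2,
                      inner_upper_arm = 2.5, inner_wrist = 2, forearm = -1.5,
                      upper_back = 0, lower_back = 0.5, shin = -1, calf = -0.5,
                      sole = 6),
    mst_kernel = c(exact = 0.50, pm1 = 0.20, pm2 = 0.05),
    pigment_kernel = c(exact = 0.20, pm1 = 0.20, pm2 = 0.20),
    undertone_kernel = c(exact = 0.20, pm1 = 0.20, pm2 = 0.20),
    fst_given_mst_sd = 2.4,
    colorimeter_fraction = 0.734,
    colorimeter_sd = c(L = 0.5, a = 0.3, b = 0.5),
    tbp_bias_wl = -0.7,
    tbp_bias_xp = 0.15,
    tbp_sd = 0.8,
    mode_offset_L = c(P_C = -2, P_NC = -1, NP_C = 3, NP_NC = 4),
    mode_offset_b = c(P_C = 2.5, P_NC = 2, NP_C = -2, NP_NC = -2.5),
    device_jitter_L = c(ipod = 11, slr = 9),
    device_jitter_b = c(ipod = 6, slr = 5),
    device_L_compression = 0.15,
    patch_size = 16L,
    patch_noise_sd = 4,
    crowd_users = 120L,
    crowd_reads_per_image = 10L,
    crowd_gold_rate = 0.20,
    crowd_skill = c(shape1 = 7, shape2 = 3),
    crowd_image_sd = 0.9,
    score_mean = c(0.060, 0.065, 0.070, 0.075, 0.080, 0.085, 0.095,
                   0.170, 0.200, 0.150),
    score_concentration = 14,
    seed = 20230322L) {
  cfg <- as.list(environment())
  kernels <- list(mst_kernel, pigment_kernel, undertone_kernel)
  for (kk in kernels) {
    if (length(kk) != 3 || any(kk < 0) ||
        abs(kk[1] + 2 * kk[2] + 2 * kk[3] - 1) > 1e-8) {
      stop_tonescale("kernel must be (exact, pm1, pm2) with exact + 2 pm1 + 2 pm2 = 1",
                     "config")
    }
  }
  if (any(diff(mst_L) >= 0)) {
    stop_tonescale("mst_L must be strictly decreasing in shade", "config")
  }
  if (length(participants_per_fst) != 6 || any(participants_per_fst < 1)) {
    stop_tonescale("participants_per_fst must give 6 positive counts", "config")
  }
  if (any(c(participant_sd_L, participant_sd_b, site_noise_L, site_noise_b,
            colorimeter_sd, tbp_sd, patch_noise_sd) < 0)) {
    stop_tonescale("SDs must be nonnegative", "config")
  }
  if (colorimeter_fraction < 0 || colorimeter_fraction > 1 ||
      crowd_gold_rate < 0 || crowd_gold_rate > 1) {
    stop_tonescale("fractions must lie in [0, 1]", "config")
  }
  if (length(score_mean) != 10 || any(score_mean <= 0 | score_mean >= 1)) {
    stop_tonescale("score_mean needs 10 values in (0, 1)", "config")
  }
  structure(cfg, class = "study_config")
}

#' Apply an ordinal rater noise kernel
#'
#' Draws an observed rating centered at the true class: exact with
#' probability `kernel[1]`, each one-step neighbor with `kernel[2]`, each
#' two-step neighbor with `kernel[3]`; out-of-range draws are clipped to
#' `1..k`.
#'
#' @param true_class Integer vector of true classes in `1..k`.
#' @param kernel Length-3 kernel `(exact, pm1, pm2)`.
#' @param k Scale size.
#' @param seed Integer seed.
#' @return Integer vector of observed ratings.
#' @export
rate_with_noise <- function(true_class, kernel, k, seed) {
  stopifnot(all(true_class >= 1 & true_class <= k))
  probs <- c(kernel[3], kernel[2], kernel[1], kernel[2], kernel[3])
  off <- with_seed(seed, sample(-2:2, length(true_class), replace = TRUE,
                                prob = probs))
  pmin(pmax(true_class + off, 1L), k)
}

#' Weighted kappa implied by a rater noise kernel
#'
#' The population linear-weighted kappa of two independent raters who each
#' apply `kernel` (with clipping) to true classes distributed as `p_true` --
#' the generating value a kappa estimate should recover on synthetic data.
#'
#' @param p_true Probability vector over true classes `1..k`.
#' @param kernel Length-3 kernel `(exact, pm1, pm2)`.
#' @param k Scale size.
#' @return The implied kappa.
#' @export
implied_kappa <- function(p_true, kernel, k) {
  stopifnot(length(p_true) == k, abs(sum(p_true) - 1) < 1e-8)
  K <- matrix(0, k, k)  # K[t, i] = P(rating i | truth t), with clipping
  mass <- c(kernel[3], kernel[2], kernel[1], kernel[2], kernel[3])
  for (t in 1:k) {
    for (o in -2:2) {
      i <- min(max(t + o, 1L), k)
      K[t, i] <- K[t, i] + mass[o + 3]
    }
  }
  P <- t(K) %*% diag(p_true) %*% K   # joint of the two raters' ratings
  w <- abs(outer(1:k, 1:k, "-")) / (k - 1)
  E <- outer(rowSums(P), colSums(P))
  1 - sum(w * P) / sum(w * E)
}

#' True site color under the generator's model
#'
#' Class mean on the MST ladder, plus the participant's deviation, the
#' anatomic site's systematic offset, and Gaussian site noise; clamped to
#' valid CIELAB ranges. With all SDs zero this returns the exact
#' class-plus-site mean.
#'
#' @param cfg A [study_config()].
#' @param mst True MST shade 1-10 (vector).
#' @param site Anatomic site name (vector; unknown names get offset 0).
#' @param participant_dev_L,participant_dev_b Participant deviations
#'   (vectors, default 0).
#' @param seed Seed for the site noise.
#' @return Matrix with columns `L`, `a`, `b`.
#' @export
true_site_color <- function(cfg, mst, site, participant_dev_L = 0,
                            participant_dev_b = 0, seed = cfg$seed) {
  n <- length(mst)
  off <- cfg$site_offset_L[site]
  off[is.na(off)] <- 0
  noise <- with_seed(seed, cbind(stats::rnorm(n, 0, cfg$site_noise_L),
                                 stats::rnorm(n, 0, cfg$site_noise_b)))
  L <- cfg$mst_L[mst] + participant_dev_L + off + noise[, 1]
  b <- cfg$mst_b[mst] + participant_dev_b + noise[, 2]
  a <- 11 + 0.04 * (50 - L)   # mild red shift for darker skin
  cbind(L = pmin(pmax(L, 0), 100),
        a = pmin(pmax(a, -127), 127),
        b = pmin(pmax(b, -127), 127))
}

#' Render a uniform-color image patch
#'
#' Converts a CIELAB base color (optionally shifted by a dermoscopy-mode
#' offset) to 8-bit sRGB and fills a square patch, adding independent
#' per-pixel Gaussian RGB noise. The per-channel median of the result
#' recovers the shifted color up to quantization.
#'
#' @param lab Length-3 true color `(L, a, b)`.
#' @param mode_offset Length-2 `(dL, db)` Lab shift, default none.
#' @param size Patch side length in pixels.
#' @param noise_sd Per-pixel RGB noise SD.
#' @param seed Integer seed.
#' @return An [image_patch()].
#' @export
render_patch <- function(lab, mode_offset = c(0, 0), size = 16L,
                         noise_sd = 0, seed = 1L) {
  shifted <- c(lab[1] + mode_offset[1], lab[2], lab[3] + mode_offset[2])
  shifted[1] <- min(max(shifted[1], 0), 100)
  base <- lab_to_rgb(shifted)
  px <- array(rep(as.numeric(base), each = size * size),
              dim = c(size, size, 3))
  if (noise_sd > 0) {
    px <- px + with_seed(seed, array(stats::rnorm(length(px), 0, noise_sd),
                                     dim = dim(px)))
  }
  image_patch(pmin(pmax(round(px), 0), 255))
}

#' Classifier scores from the class-dependent Beta model
#'
#' Malignancy scores on the 0-100 percent scale, drawn per observation from
#' a Beta distribution whose mean depends on the MST shade
#' (`score_mean[class]`, concentration `score_concentration`).
#'
#' @param cfg A [study_config()].
#' @param mst Integer MST shades 1-10.
#' @param seed Integer seed.
#' @return Numeric scores in `[0, 100]`.
#' @export
simulate_scores <- function(cfg, mst, seed = cfg$seed) {
  stopifnot(all(mst %in% 1:10))
  mu <- cfg$score_mean[mst]
  a <- mu * cfg$score_concentration
  b <- (1 - mu) * cfg$score_concentration
  100 * with_seed(seed, stats::rbeta(length(mst), a, b))
}

# pigment ladder: 15 levels spanning the cohort's L range, lightest first
.pigment_from_L <- function(cfg, L) {
  ladder <- seq(max(cfg$mst_L) + 3, min(cfg$mst_L) - 3, length.out = 15)
  vapply(L, function(x) which.min(abs(ladder - x)), integer(1))
}

#' Generate a full synthetic study
#'
#' Produces every table the analysis pipeline consumes, deterministically
#' from the config's master seed: the site-level table (ratings, colorimeter
#' triplicates, TBP re-ratings), rendered dermoscopy-style patches for
#' non-lesional sites under 4 lighting modes, the crowd read log for
#' lesional images, and the classifier score table.
#'
#' @param cfg A [study_config()].
#' @param include_images Render image patches (default `TRUE`); disable for
#'   analyses that do not need them.
#' @return Object of class `synthetic_study`: list with `sites`,
#'   `participants`, `images` (named list of patches), `images_meta`,
#'   `crowd`, `scores`, `config`.
#' @export
generate_study <- function(cfg = study_config(), include_images = TRUE) {
  stopifnot(inherits(cfg, "study_config"))
  ms <- cfg$seed

  ## --- participants: FST-balanced recruitment, MST given FST --------------
  fst <- rep(1:6, times = cfg$participants_per_fst)
  n_p <- length(fst)
  # noisy many-to-one map between the 6-level and 10-level scales: each FST
  # class spans a wide band of true MST shades (wider color variance per FST
  # class is the generator's ground truth)
  mst_center <- (fst - 0.5) * 10 / 6
  mst <- with_seed(substream_seed(ms, "mst_given_fst"), {
    pmin(pmax(round(stats::rnorm(n_p, mst_center, cfg$fst_given_mst_sd)), 1L), 10L)
  })
  dev <- with_seed(substream_seed(ms, "participant_dev"), {
    cbind(stats::rnorm(n_p, 0, cfg$participant_sd_L),
          stats::rnorm(n_p, 0, cfg$participant_sd_b))
  })
  undertone_true <- with_seed(substream_seed(ms, "undertone"), {
    pmin(pmax(round(stats::rnorm(n_p, 5.5, 2)), 1L), 10L)
  })
  n_lesions <- with_seed(substream_seed(ms, "n_lesions"), {
    sample(cfg$lesion_range[1]:cfg$lesion_range[2], n_p, replace = TRUE)
  })
  device <- with_seed(substream_seed(ms, "device"), {
    sample(c("ipod", "slr"), n_p, replace = TRUE)
  })
  colorimeter_ids <- with_seed(substream_seed(ms, "colorimeter"), {
    sample(n_p, round(cfg$colorimeter_fraction * n_p))
  })
  participants <- tibble::tibble(
    participant_id = sprintf("P%02d", seq_len(n_p)),
    fst = fst, mst_true = mst, undertone_true = undertone_true,
    dev_L = dev[, 1], dev_b = dev[, 2], n_lesions = n_lesions,
    device = device, colorimeter = seq_len(n_p) %in% colorimeter_ids)

  ## --- sites ---------------------------------------------------------------
  lesion_sites <- with_seed(substream_seed(ms, "lesion_sites"), {
    lapply(n_lesions, function(nl) sample(.nonlesional_sites, nl, replace = TRUE))
  })
  site_tab <- dplyr::bind_rows(lapply(seq_len(n_p), function(i) {
    tibble::tibble(
      participant_id = participants$participant_id[i],
      anatomic_site = c(.nonlesional_sites, lesion_sites[[i]]),
      site_kind = rep(c("nonlesional", "lesional"),
                      c(length(.nonlesional_sites), n_lesions[i])))
  }))
  site_tab$site_id <- sprintf("%s_S%02d", site_tab$participant_id,
                              stats::ave(seq_len(nrow(site_tab)),
                                         site_tab$participant_id,
                                         FUN = seq_along))
  idx <- match(site_tab$participant_id, participants$participant_id)
  site_tab$fst <- participants$fst[idx]
  mst_site <- participants$mst_true[idx]
  color <- true_site_color(cfg, mst_site, site_tab$anatomic_site,
                           participants$dev_L[idx], participants$dev_b[idx],
                           seed = substream_seed(ms, "site_color"))
  site_tab$true_L <- color[, "L"]
  site_tab$true_a <- color[, "a"]
  site_tab$true_b <- color[, "b"]
  site_tab$true_mst <- mst_site
  site_tab$true_pigment <- .pigment_from_L(cfg, site_tab$true_L)
  site_tab$true_undertone <- participants$undertone_true[idx]
  n_s <- nrow(site_tab)

  ## --- in-person ratings ---------------------------------------------------
  site_tab$mst_r1 <- rate_with_noise(site_tab$true_mst, cfg$mst_kernel, 10,
                                     substream_seed(ms, "mst_r1"))
  site_tab$mst_r2 <- rate_with_noise(site_tab$true_mst, cfg$mst_kernel, 10,
                                     substream_seed(ms, "mst_r2"))
  pig1 <- rate_with_noise(site_tab$true_pigment, cfg$pigment_kernel, 15,
                          substream_seed(ms, "pig_r1"))
  pig2 <- rate_with_noise(site_tab$true_pigment, cfg$pigment_kernel, 15,
                          substream_seed(ms, "pig_r2"))
  und1 <- rate_with_noise(site_tab$true_undertone, cfg$undertone_kernel, 10,
                          substream_seed(ms, "und_r1"))
  und2 <- rate_with_noise(site_tab$true_undertone, cfg$undertone_kernel, 10,
                          substream_seed(ms, "und_r2"))
  site_tab$pantone_r1 <- pantone_code(pig1, und1)
  site_tab$pantone_r2 <- pantone_code(pig2, und2)

  ## --- colorimeter triplicates (non-lesional sites, measured subset) ------
  meas <- participants$colorimeter[idx] & site_tab$site_kind == "nonlesional"
  trip <- with_seed(substream_seed(ms, "triplicates"), {
    lapply(1:3, function(r) {
      cbind(stats::rnorm(n_s, 0, cfg$colorimeter_sd[1]),
            stats::rnorm(n_s, 0, cfg$colorimeter_sd[2]),
            stats::rnorm(n_s, 0, cfg$colorimeter_sd[3]))
    })
  })
  for (r in 1:3) {
    site_tab[[paste0("col_L", r)]] <- ifelse(meas, site_tab$true_L + trip[[r]][, 1], NA)
    site_tab[[paste0("col_a", r)]] <- ifelse(meas, site_tab$true_a + trip[[r]][, 2], NA)
    site_tab[[paste0("col_b", r)]] <- ifelse(meas, site_tab$true_b + trip[[r]][, 3], NA)
  }

  ## --- TBP-based MST re-ratings (non-lesional sites) ----------------------
  nl <- site_tab$site_kind == "nonlesional"
  tbp <- with_seed(substream_seed(ms, "tbp"), {
    cbind(stats::rnorm(n_s, cfg$tbp_bias_xp, cfg$tbp_sd),
          stats::rnorm(n_s, cfg$tbp_bias_wl, cfg$tbp_sd))
  })
  site_tab$mst_tbp_xp <- ifelse(nl, pmin(pmax(round(site_tab$true_mst + tbp[, 1]), 1), 10), NA)
  site_tab$mst_tbp_wl <- ifelse(nl, pmin(pmax(round(site_tab$true_mst + tbp[, 2]), 1), 10), NA)

  ## --- dermoscopy patches for non-lesional sites --------------------------
  images <- list()
  images_meta <- NULL
  if (include_images) {
    nl_idx <- which(nl)
    jit_seed <- substream_seed(ms, "device_jitter")
    jit <- with_seed(jit_seed, {
      lapply(.dermoscopy_modes, function(m)
        cbind(stats::rnorm(length(nl_idx)), stats::rnorm(length(nl_idx))))
    })
    names(jit) <- .dermoscopy_modes
    meta <- list()
    for (m in .dermoscopy_modes) {
      for (j in seq_along(nl_idx)) {
        i <- nl_idx[j]
        dev_nm <- participants$device[idx[i]]
        lab <- c(55 + cfg$device_L_compression * (site_tab$true_L[i] - 55) +
                   jit[[m]][j, 1] * cfg$device_jitter_L[[dev_nm]],
                 site_tab$true_a[i],
                 site_tab$true_b[i] +
                   jit[[m]][j, 2] * cfg$device_jitter_b[[dev_nm]])
        key <- paste0(site_tab$site_id[i], "_", m)
        images[[key]] <- render_patch(
          lab, c(cfg$mode_offset_L[[m]], cfg$mode_offset_b[[m]]),
          size = cfg$patch_size, noise_sd = cfg$patch_noise_sd,
          seed = substream_seed(ms, key))
        meta[[key]] <- tibble::tibble(image_id = key,
                                      site_id = site_tab$site_id[i],
                                      mode = m, device = dev_nm)
      }
    }
    images_meta <- dplyr::bind_rows(meta)
  }

  ## --- crowd log over lesional images --------------------------------------
  lesional <- site_tab[site_tab$site_kind == "lesional", , drop = FALSE]
  skill <- with_seed(substream_seed(ms, "skill"), {
    stats::rbeta(cfg$crowd_users, cfg$crowd_skill[1], cfg$crowd_skill[2])
  })
  gold <- with_seed(substream_seed(ms, "gold"), {
    stats::runif(nrow(lesional)) < cfg$crowd_gold_rate
  })
  # every reader of an image sees the same lighting/site-distorted apparent
  # FST; skill governs how faithfully a read reports that shared percept.
  # Crowd-vs-in-person concordance is therefore capped by the image
  # distortion, not by annotator skill
  crowd <- with_seed(substream_seed(ms, "crowd"), {
    perceived <- pmin(pmax(as.integer(round(lesional$fst +
      stats::rnorm(nrow(lesional), 0, cfg$crowd_image_sd))), 1L), 6L)
    rows <- lapply(seq_len(nrow(lesional)), function(im) {
      users <- sample(cfg$crowd_users, cfg$crowd_reads_per_image)
      seen <- perceived[im]
      lab <- vapply(users, function(u) {
        if (stats::runif(1) < skill[u]) return(seen)
        o <- sample(c(-2L, -1L, 1L, 2L), 1, prob = c(0.1, 0.4, 0.4, 0.1))
        min(max(seen + o, 1L), 6L)
      }, integer(1))
      tibble::tibble(user_id = sprintf("U%03d", users),
                     image_id = lesional$site_id[im],
                     label = lab, is_gold = gold[im],
                     gold_label = if (gold[im]) lesional$fst[im] else NA_integer_)
    })
    log <- dplyr::bind_rows(rows)
    log$order <- sample(nrow(log))
    log[order(log$order), , drop = FALSE]
  })

  ## --- classifier scores for lesional sites -------------------------------
  scores <- tibble::tibble(
    lesion_id = lesional$site_id,
    score = simulate_scores(cfg, lesional$true_mst,
                            seed = substream_seed(ms, "scores")),
    fst = lesional$fst,
    mst = lesional$true_mst)

  structure(list(sites = site_tab, participants = participants,
                 images = images, images_meta = images_meta,
                 crowd = crowd, scores = scores, config = cfg),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d participants, %d sites (%d lesional), %d crowd reads\n",
              nrow(x$participants), nrow(x$sites),
              sum(x$sites$site_kind == "lesional"), nrow(x$crowd)))
  invisible(x)
}
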