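# Orchestration of the four analyses over the site-level table, images,
# crowd log and score table: in-person reliability, cluster dispersion in
# colorimeter space, photography-based reliability, and fairness auditing.

.sites_schema <- c("participant_id", "site_id", "site_kind", "anatomic_site",
                   "fst", "mst_r1", "mst_r2", "pantone_r1", "pantone_r2",
                   "col_L1", "col_a1", "col_b1", "col_L2", "col_a2", "col_b2",
                   "col_L3", "col_a3", "col_b3", "mst_tbp_xp", "mst_tbp_wl")

#' Read / write the site-level table
#'
#' One row per skin site: identifiers, lesional flag, anatomic site, FST,
#' two raters' MST and Pantone-style ratings, colorimeter Lab triplicates
#' (empty where unmeasured) and TBP-based MST re-ratings. Empty cells are
#' written as empty strings and read back as `NA`.
#'
#' @param path CSV path.
#' @return `read_sites()`: a tibble; `write_sites()`: `path` invisibly.
#' @export
read_sites <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  missing <- setdiff(.sites_schema, names(df))
  if (length(missing)) {
    stop_tonescale(paste("sites table missing columns:",
                         paste(missing, collapse = ", ")), "schema")
  }
  tibble::as_tibble(df)
}

#' @rdname read_sites
#' @param sites Site-level tibble (e.g. `generate_study()$sites`).
#' @export
write_sites <- function(sites, path) {
  out <- sites[, intersect(c(.sites_schema,
                             setdiff(names(sites), .sites_schema)),
                           names(sites))]
  out <- out[, !grepl("^true_", names(out))]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

# colorimeter ITA per triplicate; NA where unmeasured or near-neutral
.triplicate_ita <- function(sites) {
  one <- function(L, b) {
    ifelse(is.na(L) | is.na(b) | abs(b) < 1e-6, NA_real_,
           atan((L - 50) / b) * 180 / pi)
  }
  cbind(one(sites$col_L1, sites$col_b1),
        one(sites$col_L2, sites$col_b2),
        one(sites$col_L3, sites$col_b3))
}

.icc_by_stratum <- function(sites, ita) {
  icc_of <- function(idx) {
    m <- ita[idx, , drop = FALSE]
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(m) < 2) return(list(icc = NA_real_, n = nrow(m)))
    list(icc = tryCatch(icc_agreement(m), tonescale_error = function(e) NA_real_),
         n = nrow(m))
  }
  strata <- sort(unique(sites$anatomic_site[sites$site_kind == "nonlesional"]))
  rows <- lapply(strata, function(s) {
    r <- icc_of(which(sites$site_kind == "nonlesional" &
                        sites$anatomic_site == s))
    tibble::tibble(stratum = s, icc = r$icc, n = r$n)
  })
  les <- icc_of(which(sites$site_kind == "lesional"))
  all <- icc_of(seq_len(nrow(sites)))
  dplyr::bind_rows(c(rows, list(
    tibble::tibble(stratum = "lesional", icc = les$icc, n = les$n),
    tibble::tibble(stratum = "all_sites", icc = all$icc, n = all$n))))
}

#' In-person reliability analysis
#'
#' Per-site inter-rater agreement (linear-weighted kappa) for MST, Pantone
#' pigment and Pantone undertone, restricted to sites both raters rated,
#' plus the ICC of colorimeter triplicate ITA by site stratum.
#'
#' @param sites Site-level tibble (see [read_sites()]).
#' @return List of tibbles: `mst`, `pantone_pigment`, `pantone_undertone`,
#'   `colorimeter_icc`.
#' @export
run_inperson_reliability <- function(sites) {
  les <- sites$site_kind == "lesional"
  p1 <- parse_pantone_safe(sites$pantone_r1)
  p2 <- parse_pantone_safe(sites$pantone_r2)
  mk <- function(a, b) tibble::tibble(rating_a = a, rating_b = b,
                                      anatomic_site = sites$anatomic_site,
                                      lesional = les)
  list(
    mst = agreement_by_site(mk(sites$mst_r1, sites$mst_r2), k = 10),
    pantone_pigment = agreement_by_site(mk(p1$pigment, p2$pigment), k = 15),
    pantone_undertone = agreement_by_site(mk(p1$undertone, p2$undertone), k = 10),
    colorimeter_icc = .icc_by_stratum(sites, .triplicate_ita(sites)))
}

# parse codes with NAs passed through
parse_pantone_safe <- function(code) {
  out <- list(pigment = rep(NA_integer_, length(code)),
              undertone = rep(NA_integer_, length(code)))
  ok <- !is.na(code)
  if (any(ok)) {
    p <- parse_pantone(code[ok])
    out$pigment[ok] <- p$pigment
    out$undertone[ok] <- p$undertone
  }
  out
}

#' Cluster dispersion of subjective scales in colorimeter space
#'
#' Filters to non-lesional, colorimeter-measured sites with at least one
#' MST and one Pantone rating; takes the triplicate-mean `(L*, b*)` as the
#' objective 2D color estimate; selects one rating per site at random where
#' both raters rated (seeded); and computes a [dispersion_report()] per
#' scale (FST, MST, full Pantone swatch code) on the identical point set.
#'
#' @param sites Site-level tibble.
#' @param seed Seed for the random rater selection (recorded in the
#'   result).
#' @param by_site Also compute per-anatomic-site reports.
#' @return List with `reports` (named list of dispersion reports), `points`,
#'   `labels`, `n`, `seed`.
#' @export
run_dispersion <- function(sites, seed = 1L, by_site = FALSE) {
  has_col <- !is.na(sites$col_L1) & !is.na(sites$col_L2) & !is.na(sites$col_L3)
  keep <- sites$site_kind == "nonlesional" & has_col &
    (!is.na(sites$mst_r1) | !is.na(sites$mst_r2)) &
    (!is.na(sites$pantone_r1) | !is.na(sites$pantone_r2))
  d <- sites[keep, , drop = FALSE]
  if (nrow(d) < 3) stop_tonescale("too few filter-surviving sites", "too_few")
  points <- cbind(L = rowMeans(cbind(d$col_L1, d$col_L2, d$col_L3)),
                  b = rowMeans(cbind(d$col_b1, d$col_b2, d$col_b3)))
  mst <- select_single_rating(d$mst_r1, d$mst_r2,
                              seed = substream_seed(seed, "mst_pick"))
  pantone <- select_single_rating(d$pantone_r1, d$pantone_r2,
                                  seed = substream_seed(seed, "pantone_pick"))
  labels <- list(fst = as.character(d$fst), mst = as.character(mst),
                 pantone = pantone)
  reports <- dispersion_compare(points, labels,
                                sites = if (by_site) d$anatomic_site else NULL)
  list(reports = reports, points = points, labels = labels,
       n = nrow(d), seed = seed)
}

#' Photography-based reliability analysis
#'
#' Compares in-person ratings with photography-derived ones: per-site
#' kappa of TBP-based MST (XP and WL) against Rater 1's in-person MST with
#' paired mean-difference tests of the lighting bias; ICC of
#' image-extracted ITA against colorimeter ITA per dermoscopy mode and
#' device; and crowd majority FST labels against in-person FST (kappa,
#' concordance, accuracy-by-site chi-squared).
#'
#' @param sites Site-level tibble.
#' @param study Optional `synthetic_study` carrying `images`,
#'   `images_meta` and `crowd`; image and crowd analyses are skipped when
#'   absent.
#' @param crowd_percentile,crowd_window Passed to [qualify_reads()].
#' @return List with `tbp_kappa` (tibble per mode), `tbp_bias` (paired
#'   t results per mode), `image_icc` (tibble), `crowd` (list), as
#'   available.
#' @export
run_photo_reliability <- function(sites, study = NULL,
                                  crowd_percentile = 80, crowd_window = 50) {
  nl <- sites$site_kind == "nonlesional"
  out <- list()

  tbp_tab <- function(col) {
    d <- tibble::tibble(rating_a = sites$mst_r1[nl],
                        rating_b = sites[[col]][nl],
                        anatomic_site = sites$anatomic_site[nl],
                        lesional = FALSE)
    agreement_by_site(d[stats::complete.cases(d[, 1:2]), ], k = 10)
  }
  out$tbp_kappa <- list(xp = tbp_tab("mst_tbp_xp"), wl = tbp_tab("mst_tbp_wl"))
  bias <- function(col) {
    ok <- nl & !is.na(sites$mst_r1) & !is.na(sites[[col]])
    paired_mean_difference(sites$mst_r1[ok], sites[[col]][ok])
  }
  out$tbp_bias <- list(xp = bias("mst_tbp_xp"), wl = bias("mst_tbp_wl"))

  if (!is.null(study) && length(study$images)) {
    col_ita <- {
      ita <- .triplicate_ita(sites)
      rowMeans(ita)
    }
    names(col_ita) <- sites$site_id
    meta <- study$images_meta
    img_ita <- vapply(meta$image_id, function(id) {
      tryCatch(image_ita(study$images[[id]]),
               tonescale_error = function(e) NA_real_)
    }, numeric(1))
    meta$img_ita <- img_ita
    meta$col_ita <- col_ita[meta$site_id]
    cells <- split(meta, list(meta$mode, meta$device))
    out$image_icc <- dplyr::bind_rows(lapply(cells, function(cc) {
      m <- cbind(cc$col_ita, cc$img_ita)
      m <- m[stats::complete.cases(m), , drop = FALSE]
      icc <- if (nrow(m) < 2) NA_real_ else
        tryCatch(icc_agreement(m), tonescale_error = function(e) NA_real_)
      tibble::tibble(mode = cc$mode[1], device = cc$device[1],
                     icc = icc, n = nrow(m))
    }))
  }

  if (!is.null(study) && !is.null(study$crowd) && nrow(study$crowd)) {
    q <- qualify_reads(study$crowd, percentile = crowd_percentile,
                       window = crowd_window)
    maj <- aggregate_crowd(q)
    ref <- tibble::tibble(image_id = sites$site_id, reference = sites$fst)
    cmp <- crowd_vs_reference(maj, ref, k = 6)
    resolved <- merge(maj[!is.na(maj$label), ],
                      sites[, c("site_id", "fst", "anatomic_site")],
                      by.x = "image_id", by.y = "site_id")
    acc_tab <- table(resolved$anatomic_site, resolved$label == resolved$fst)
    acc_tab <- acc_tab[rowSums(acc_tab) > 0, , drop = FALSE]
    chi <- if (ncol(acc_tab) == 2 && nrow(acc_tab) >= 2) {
      chi_squared_independence(acc_tab)
    } else NULL
    les_sites <- sites[sites$site_kind == "lesional", , drop = FALSE]
    pairs <- merge(maj[!is.na(maj$label), ],
                   tibble::tibble(image_id = les_sites$site_id,
                                  fst = les_sites$fst,
                                  anatomic_site = les_sites$anatomic_site),
                   by = "image_id")
    kappa_by_site <- agreement_by_site(
      tibble::tibble(rating_a = pairs$fst, rating_b = pairs$label,
                     anatomic_site = pairs$anatomic_site, lesional = FALSE),
      k = 6)
    out$crowd <- list(majority = maj, comparison = cmp,
                      accuracy_by_site_chisq = chi,
                      kappa_by_site = kappa_by_site)
  }
  out
}

#' Fairness analysis of classifier scores
#'
#' One [fairness_report()] per labeling scheme on the same score table.
#' Classes with no scores are omitted with a warning.
#'
#' @param scores Tibble with columns `lesion_id`, `score`, `fst`, `mst`.
#' @return List of fairness reports, named `fst` and `mst`.
#' @export
run_fairness <- function(scores) {
  stopifnot(all(c("score", "fst", "mst") %in% names(scores)))
  list(fst = fairness_report(scores$score, scores$fst, scale = "fst"),
       mst = fairness_report(scores$score, scores$mst, scale = "mst"))
}

#' Run the full pipeline on a synthetic study
#'
#' Generates a study from `cfg` and runs all four analyses; optionally
#' writes tables (CSV), reports (JSON) and the run manifest to `out_dir`.
#'
#' @param cfg A [study_config()].
#' @param out_dir Optional output directory.
#' @param dispersion_seed Seed for the random rater selection.
#' @return List with `study`, `inperson`, `dispersion`, `photo`,
#'   `fairness`, `manifest`.
#' @export
run_study <- function(cfg = study_config(), out_dir = NULL,
                      dispersion_seed = cfg$seed) {
  study <- generate_study(cfg)
  inperson <- run_inperson_reliability(study$sites)
  disp <- run_dispersion(study$sites, seed = dispersion_seed)
  photo <- run_photo_reliability(study$sites, study)
  fair <- run_fairness(study$scores)
  manifest <- list(
    master_seed = cfg$seed,
    dispersion_seed = dispersion_seed,
    n_participants = nrow(study$participants),
    n_sites = nrow(study$sites),
    n_dispersion_sites = disp$n,
    n_crowd_reads = nrow(study$crowd),
    n_scores = nrow(study$scores),
    generated_at = format(Sys.time(), tz = "UTC"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_sites(study$sites, file.path(out_dir, "sites.csv"))
    utils::write.csv(study$crowd, file.path(out_dir, "crowd.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(study$scores, file.path(out_dir, "scores.csv"),
                     row.names = FALSE, na = "")
    rep_json <- list(
      dispersion = lapply(disp$reports, function(r) if (is.null(r)) NULL else
        list(scale = r$scale, dbi = r$dbi, rsi = r$rsi, n = r$n,
             classes = r$classes)),
      fairness = lapply(fair, function(r)
        list(scale = r$scale, by_delta = r$by_delta,
             percentiles = r$percentiles)),
      manifest = manifest)
    jsonlite::write_json(rep_json, file.path(out_dir, "reports.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(study = study, inperson = inperson, dispersion = disp,
       photo = photo, fairness = fair, manifest = manifest)
}
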