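#' Cohort configuration
#'
#' Parameters of the virtual patient cohort: per-kidney parenchymal volume,
#' the link model tying a ground-truth volume-weighted metric to split
#' kidney function, BSA-based conversion between true (ml/min) and
#' BSA-normalised (ml/min/1.73m^2) measured GFR, the eGFR noise model, and
#' proteinuria prevalence with its multiplicative parameter shifts.
#'
#' The link model is
#' `split mGFRt = intercept + slope * (V x Dtax) + N(0, residual_sd)`,
#' where `V x Dtax` is the kidney's volume times its ground-truth axial
#' diffusivity in the driver context (medulla / bipolar / diastole, where
#' the volume-weighted axial-diffusivity correlation with split kidney
#' function peaks). Exactly one of `residual_sd` / `target_r` is used to set
#' the residual scale: with `target_r`, `residual_sd` is calibrated as
#' `|slope| * sd(V x Dtax) * sqrt(1/r^2 - 1)`. Supplying both triggers an
#' attainability check.
#'
#' @param n_subjects number of subjects (>= 2); each contributes 2 kidneys.
#' @param volume_mean,volume_sd per-kidney parenchymal volume (ml).
#' @param link list with `intercept`, `slope`, and `residual_sd` or
#'   `target_r`.
#' @param bsa_mean,bsa_sd body surface area (m^2) for
#'   `mGFR = mGFRt * 1.73 / BSA`.
#' @param egfr_target_r target Pearson correlation between eGFR and total
#'   mGFR (noise on eGFR is calibrated to it).
#' @param proteinuria_prevalence subject-level probability of proteinuria.
#' @param proteinuria_shifts named list of multiplicative shifts applied to
#'   the ground-truth metrics of proteinuria-positive subjects
#'   (`diffusivity` covers MD/Dtax/Dtrad, plus `fp`, `dp`, `fa`).
#' @param subject_icc share of latent kidney-function variance at the
#'   subject level (drives within-subject correlation of the two kidneys).
#' @param metric_loading loading of each ground-truth metric on the latent
#'   kidney function score.
#' @param seed integer; fixes all randomness of [make_cohort()].
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 27,
                          volume_mean = 160, volume_sd = 35,
                          link = list(intercept = 5, slope = 0.1,
                                      target_r = 0.8),
                          bsa_mean = 1.9, bsa_sd = 0.2,
                          egfr_target_r = 0.735,
                          proteinuria_prevalence = 4 / 26,
                          proteinuria_shifts = list(diffusivity = -0.068,
                                                    fp = -0.386,
                                                    dp = -0.468,
                                                    fa = -0.177),
                          subject_icc = 0.5, metric_loading = 0.6,
                          seed = 1L) {
  if (n_subjects < 2) stop("need at least 2 subjects")
  if (volume_mean <= 0 || volume_sd < 0) stop("invalid volume distribution")
  has_sd <- !is.null(link$residual_sd)
  has_r <- !is.null(link$target_r)
  if (!has_sd && !has_r)
    stop("link must supply residual_sd or target_r")
  if (has_r && (link$target_r <= -1 || link$target_r >= 1))
    stop("target_r must lie in (-1, 1)")
  if (has_sd && link$residual_sd < 0) stop("residual_sd must be >= 0")
  if (subject_icc < 0 || subject_icc > 1) stop("subject_icc must be in [0, 1]")
  if (abs(metric_loading) > 1) stop("metric_loading must be in [-1, 1]")
  structure(list(n_subjects = as.integer(n_subjects),
                 volume_mean = volume_mean, volume_sd = volume_sd,
                 link = link, bsa_mean = bsa_mean, bsa_sd = bsa_sd,
                 egfr_target_r = egfr_target_r,
                 proteinuria_prevalence = proteinuria_prevalence,
                 proteinuria_shifts = proteinuria_shifts,
                 subject_icc = subject_icc, metric_loading = metric_loading,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a virtual cohort
#'
#' Draws per-kidney ground-truth REFMAP metrics for all eight
#' tissue/waveform/phase contexts around the configured tissue means, with
#' a latent kidney-function score shared between a subject's kidneys
#' (`subject_icc`) loading on every metric (`metric_loading`), applies the
#' multiplicative proteinuria shifts to positive subjects, then links split
#' kidney function to the volume-weighted axial diffusivity of the driver
#' context and derives total/split mGFRt, SRF (which sums to 1 per subject
#' by construction), BSA-normalised mGFR, and a noisy eGFR calibrated to a
#' target eGFR-mGFR correlation.
#'
#' @param config a [cohort_config()].
#' @param phantom optional [phantom_config()] used when writing DWI bundles.
#' @param out_dir optional output directory: writes `subjects.tsv`,
#'   `kidney_metrics.tsv`, a YAML dump of the configuration, and (for the
#'   first `write_dwi` subjects) per-kidney 4-quadrant DWI + masks.
#' @param write_dwi number of subjects for which full DWI bundles are
#'   written (0 disables; DWI synthesis is the expensive part).
#' @return list of class `virtual_cohort` with `subjects` (one row per
#'   kidney: subject_id, side, volume_ml, eGFR, mGFR, mGFRt, SRF,
#'   proteinuria — GFR columns hold subject totals, split values come from
#'   [split_function()]), `kidney_metrics` (long table of ground-truth
#'   metrics per kidney x context) and `config`.
#' @export
make_cohort <- function(config = cohort_config(), phantom = phantom_config(),
                        out_dir = NULL, write_dwi = 0L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  tp <- default_tissue_params()
  ids <- sprintf("S%03d", seq_len(n))
  sides <- c("L", "R")

  # latent kidney function score: subject component + kidney component
  z_subj <- stats::rnorm(n)
  z_kid <- matrix(stats::rnorm(2 * n), n, 2)
  z <- sqrt(config$subject_icc) * z_subj +
    sqrt(1 - config$subject_icc) * z_kid

  prot <- stats::rbinom(n, 1, config$proteinuria_prevalence)
  vol <- matrix(pmax(stats::rnorm(2 * n, config$volume_mean, config$volume_sd),
                     30), n, 2)

  lo <- config$metric_loading
  sh <- config$proteinuria_shifts
  km <- vector("list", nrow(tp))
  for (r in seq_len(nrow(tp))) {
    row <- tp[r, ]
    draw <- function(mean, sd, lower, upper = Inf) {
      eps <- matrix(stats::rnorm(2 * n), n, 2)
      pmin(pmax(mean + sd * (lo * z + sqrt(1 - lo^2) * eps), lower), upper)
    }
    md <- draw(row$md_mean, row$md_sd, 0.2)
    fa <- draw(row$fa_mean, row$fa_sd, 0.01, 0.9)
    fp <- draw(row$fp_mean, row$fp_sd, 0.005, 1)
    dp <- draw(row$dp_mean, row$dp_sd, 3)
    dmul <- ifelse(prot == 1, 1 + sh$diffusivity, 1)
    md <- md * dmul
    fa <- fa * ifelse(prot == 1, 1 + sh$fa, 1)
    fp <- fp * ifelse(prot == 1, 1 + sh$fp, 1)
    dp <- dp * ifelse(prot == 1, 1 + sh$dp, 1)
    lam <- eigenvalues_from_md_fa(as.vector(md), as.vector(fa))
    km[[r]] <- data.frame(
      subject_id = rep(ids, 2), side = rep(sides, each = n),
      tissue = row$tissue, waveform = row$waveform, phase = row$phase,
      MD = as.vector(md), FA = as.vector(fa),
      Dtax = lam[, 1], Dtrad = (lam[, 2] + lam[, 3]) / 2,
      fp = as.vector(fp), Dp = as.vector(dp),
      stringsAsFactors = FALSE)
  }
  kidney_metrics <- do.call(rbind, km)

  driver <- kidney_metrics[kidney_metrics$tissue == "medulla" &
                             kidney_metrics$waveform == "bipolar" &
                             kidney_metrics$phase == "diastole", ]
  driver <- driver[order(driver$subject_id, driver$side), ]
  dtax <- matrix(NA_real_, n, 2, dimnames = list(ids, sides))
  dtax[cbind(match(driver$subject_id, ids), match(driver$side, sides))] <-
    driver$Dtax
  vd <- vol * dtax

  link <- config$link
  if (!is.null(link$target_r)) {
    sd_needed <- abs(link$slope) * stats::sd(as.vector(vd)) *
      sqrt(1 / link$target_r^2 - 1)
    if (!is.null(link$residual_sd)) {
      r_implied <- 1 / sqrt(1 + (link$residual_sd /
                                   (abs(link$slope) * stats::sd(as.vector(vd))))^2)
      if (abs(r_implied - link$target_r) > 0.05)
        stop(sprintf(
          "target correlation %.3f unattainable: residual_sd %.3g implies r = %.3f",
          link$target_r, link$residual_sd, r_implied))
      resid_sd <- link$residual_sd
    } else resid_sd <- sd_needed
  } else resid_sd <- link$residual_sd

  mgfrt_split <- link$intercept + link$slope * vd +
    matrix(stats::rnorm(2 * n, 0, resid_sd), n, 2)
  mgfrt_split <- pmax(mgfrt_split, 0.5)
  mgfrt_total <- rowSums(mgfrt_split)
  srf <- mgfrt_split / mgfrt_total

  bsa <- pmax(stats::rnorm(n, config$bsa_mean, config$bsa_sd), 1.2)
  mgfr_total <- mgfrt_total * 1.73 / bsa

  r_e <- config$egfr_target_r
  egfr <- mgfr_total + stats::rnorm(n, 0, stats::sd(mgfr_total) *
                                      sqrt(1 / r_e^2 - 1))
  egfr <- pmax(egfr, 1)

  subjects <- data.frame(
    subject_id = rep(ids, 2), side = rep(sides, each = n),
    volume_ml = as.vector(vol), eGFR = rep(egfr, 2),
    mGFR = rep(mgfr_total, 2), mGFRt = rep(mgfrt_total, 2),
    SRF = as.vector(srf), proteinuria = rep(prot, 2),
    stringsAsFactors = FALSE)
  subjects <- subjects[order(subjects$subject_id, subjects$side), ]
  rownames(subjects) <- NULL

  out <- structure(list(subjects = subjects, kidney_metrics = kidney_metrics,
                        resid_sd = resid_sd, config = config),
                   class = "virtual_cohort")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_subject_table(subjects, file.path(out_dir, "subjects.tsv"))
    utils::write.table(kidney_metrics,
                       file.path(out_dir, "kidney_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_config(list(cohort = unclass(config)[!vapply(unclass(config), is.function, TRUE)]),
                 file.path(out_dir, "config.yaml"))
    nw <- min(write_dwi, n)
    if (nw > 0) {
      qs <- quadrants()
      for (s in seq_len(nw)) for (side in sides) {
        ph <- phantom
        ph$seed <- config$seed + 1000L * s + 100L * (side == "R")
        maps <- make_phantom(ph)
        kdir <- file.path(out_dir, sprintf("%s_%s", ids[s], side))
        dir.create(kdir, showWarnings = FALSE)
        write_mask(maps$masks$cortex, file.path(kdir, "cortex.nii.gz"))
        write_mask(maps$masks$medulla, file.path(kdir, "medulla.nii.gz"))
        write_mask(maps$masks$excluded, file.path(kdir, "excluded.nii.gz"))
        for (q in seq_len(nrow(qs))) {
          sch <- study_scheme(qs$waveform[q], qs$phase[q])
          ser <- synthesize_dwi(maps, sch, seed = ph$seed + q)
          write_series(ser, file.path(kdir, paste0(qs$quadrant[q], ".nii.gz")))
        }
      }
    }
  }
  out
}

#' @export
print.virtual_cohort <- function(x, ...) {
  cat(sprintf("<virtual_cohort> %d subjects (%d kidneys), %d proteinuria-positive\n",
              x$config$n_subjects, nrow(x$subjects),
              sum(x$subjects$proteinuria[!duplicated(x$subjects$subject_id)])))
  invisible(x)
}
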