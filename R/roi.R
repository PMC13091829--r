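#' ROI means of parametric maps
#'
#' Arithmetic mean of each metric map over the valid voxels of a tissue
#' mask. Voxels carrying an excluded label (lesion, cyst, renal pelvis,
#' vessel) never contribute. Validity is metric-family-specific:
#' pseudodiffusivity-family metrics (`Dp`, `Dp_ax`, `Dp_rad`) additionally
#' drop voxels whose perfusion fraction was below the floor
#' (`dp_undefined`), while tissue-diffusivity metrics only drop failed
#' voxels; with map inputs this is carried by their NA pattern and the
#' optional `status` map.
#'
#' @param maps named list of 3D metric maps (e.g. from [fit_ivim()] or
#'   [refmap_fit()]); non-numeric or QC entries are ignored.
#' @param masks a [mask_set()].
#' @param tissue `"cortex"` or `"medulla"`.
#' @param status optional character status map; when present, voxels with
#'   status `"failed"` are dropped for every metric and `"dp_undefined"`
#'   voxels are dropped for the Dp family only.
#' @return data.frame with one row per metric: `metric`, `mean`, `n_valid`.
#'   Metrics with zero valid voxels get an NA mean (and are reported, not
#'   dropped silently).
#' @export
summarize_roi <- function(maps, masks, tissue = c("cortex", "medulla"),
                          status = NULL) {
  tissue <- match.arg(tissue)
  stopifnot(inherits(masks, "mask_set"))
  roi <- masks[[tissue]] & !masks$excluded
  if (!any(roi)) stop(sprintf("no %s voxels after exclusions", tissue))
  if (is.null(status) && !is.null(maps$status)) status <- maps$status
  dp_family <- c("Dp", "Dp_ax", "Dp_rad")
  keep <- vapply(maps, function(m)
    is.numeric(m) && identical(dim(m), dim(roi)), TRUE)
  maps <- maps[keep]
  out <- lapply(names(maps), function(nm) {
    sel <- roi
    if (!is.null(status)) {
      sel <- sel & !is.na(status) & status != "failed"
      if (nm %in% dp_family) sel <- sel & status != "dp_undefined"
    }
    v <- maps[[nm]][sel]
    v <- v[is.finite(v)]
    data.frame(metric = nm, mean = if (length(v)) mean(v) else NA_real_,
               n_valid = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Volume-weight ROI metrics
#'
#' Multiplies every ROI-mean metric by the kidney's parenchymal volume,
#' `V*metric = V x mean(metric)` — combining tissue quality with gross
#' kidney volume. Linear in V by definition.
#'
#' @param record data.frame from [summarize_roi()] (columns `metric`,
#'   `mean`).
#' @param volume_ml parenchymal volume in ml (> 0).
#' @return the record with an added `v_weighted` column.
#' @export
volume_weight <- function(record, volume_ml) {
  if (is.null(volume_ml) || length(volume_ml) != 1L || is.na(volume_ml))
    stop("volume_ml is required")
  if (volume_ml <= 0) stop("volume_ml must be > 0")
  record$v_weighted <- volume_ml * record$mean
  record
}

#' Split kidney function
#'
#' Single-kidney GFR obtained by multiplying total GFR by the kidney's
#' split renal function fraction; applied to both the BSA-normalised mGFR
#' (ml/min/1.73m^2) and the true mGFRt (ml/min). Splits over both sides sum
#' to the totals exactly.
#'
#' @param mGFR_total,mGFRt_total subject-level totals.
#' @param SRF_side split renal function fraction of this kidney, in
#'   `[0, 1]`.
#' @return list with `mGFR_split` and `mGFRt_split`.
#' @export
split_function <- function(mGFR_total, mGFRt_total, SRF_side) {
  if (any(SRF_side < 0 | SRF_side > 1, na.rm = TRUE))
    stop("SRF must lie in [0, 1]")
  list(mGFR_split = mGFR_total * SRF_side,
       mGFRt_split = mGFRt_total * SRF_side)
}

#' Per-kidney, per-tissue summary records for a fitted kidney
#'
#' Convenience wrapper building the long-format record the statistics layer
#' consumes: ROI means for both tissues, volume weighting, and split GFR
#' columns from the subject table row.
#'
#' @param maps named list of metric maps for one kidney and quadrant.
#' @param masks a [mask_set()].
#' @param subject_row one row of a subject table (see
#'   [read_subject_table()]).
#' @param waveform,phase quadrant tag to stamp on the records.
#' @return data.frame, one row per tissue x metric, with identifiers, ROI
#'   mean, `v_weighted`, and split GFR columns.
#' @export
kidney_record <- function(maps, masks, subject_row,
                          waveform = "bipolar", phase = "diastole") {
  stopifnot(nrow(subject_row) == 1L)
  rows <- lapply(c("cortex", "medulla"), function(tis) {
    rec <- summarize_roi(maps, masks, tis)
    rec <- volume_weight(rec, subject_row$volume_ml)
    rec$tissue <- tis
    rec
  })
  rec <- do.call(rbind, rows)
  spl <- split_function(subject_row$mGFR, subject_row$mGFRt, subject_row$SRF)
  rec$subject_id <- subject_row$subject_id
  rec$side <- subject_row$side
  rec$waveform <- waveform
  rec$phase <- phase
  rec$volume_ml <- subject_row$volume_ml
  rec$mGFR_split <- spl$mGFR_split
  rec$mGFRt_split <- spl$mGFRt_split
  rec$eGFR <- subject_row$eGFR
  rec$proteinuria <- subject_row$proteinuria
  rec
}
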