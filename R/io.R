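#' Construct a DWI series
#'
#' A 4D signal array bound to its acquisition scheme and, optionally, a mask
#' set. Signals are magnitude MRI values (>= 0).
#'
#' @param signal 4D numeric array (x, y, z, volume).
#' @param scheme an [acq_scheme()] whose length matches `dim(signal)[4]`.
#' @param voxdim voxel size in mm (length 3).
#' @param masks optional [mask_set()].
#' @return An object of class `dwi_series`.
#' @export
dwi_series <- function(signal, scheme, voxdim = c(2.2, 2.2, 5), masks = NULL) {
  signal <- as.array(signal)
  if (length(dim(signal)) != 4L)
    stop("signal must be a 4D array (x, y, z, volume)")
  if (!inherits(scheme, "acq_scheme")) stop("scheme must be an acq_scheme")
  if (dim(signal)[4] != length(scheme$bval))
    stop(sprintf("volume count (%d) does not match scheme length (%d)",
                 dim(signal)[4], length(scheme$bval)))
  if (any(signal < 0)) stop("magnitude signals must be >= 0")
  structure(list(signal = signal, scheme = scheme,
                 voxdim = as.numeric(voxdim), masks = masks),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<dwi_series> %dx%dx%d, %d volumes, %s / %s\n",
              d[1], d[2], d[3], d[4], x$scheme$waveform, x$scheme$phase))
  invisible(x)
}

#' Construct a mask set
#'
#' Tissue masks voxel-aligned to a DWI grid. Cortex and medulla must be
#' disjoint and contained in the parenchyma; excluded structures (lesion,
#' cyst, renal pelvis, vessels) must be disjoint from the parenchyma and
#' never contribute to ROI statistics.
#'
#' @param cortex,medulla,excluded logical (or 0/1) 3D arrays; `excluded` and
#'   `parenchyma` are optional.
#' @param parenchyma defaults to `cortex | medulla`.
#' @return An object of class `mask_set`.
#' @export
mask_set <- function(cortex, medulla, excluded = NULL, parenchyma = NULL) {
  cortex <- array(as.logical(cortex), dim(as.array(cortex)))
  medulla <- array(as.logical(medulla), dim(as.array(medulla)))
  if (!identical(dim(cortex), dim(medulla)))
    stop("cortex and medulla masks must share a grid")
  if (is.null(excluded)) excluded <- array(FALSE, dim(cortex))
  excluded <- array(as.logical(excluded), dim(as.array(excluded)))
  if (is.null(parenchyma)) parenchyma <- cortex | medulla
  parenchyma <- array(as.logical(parenchyma), dim(as.array(parenchyma)))
  if (any(cortex & medulla)) stop("cortex and medulla masks overlap")
  if (any((cortex | medulla) & !parenchyma))
    stop("cortex/medulla must lie within the parenchyma mask")
  if (any(excluded & parenchyma))
    stop("excluded structures must be disjoint from the parenchyma")
  structure(list(cortex = cortex, medulla = medulla,
                 excluded = excluded, parenchyma = parenchyma),
            class = "mask_set")
}

# ---- FSL-dialect gradient tables ------------------------------------------

#' Read / write FSL-style .bval and .bvec files
#'
#' `.bval` holds one whitespace-separated row of b-values in s/mm^2; `.bvec`
#' holds three rows (x, y, z components in image coordinates).
#'
#' @param path file path.
#' @name gradient_tables
#' @export
read_bval <- function(path) {
  v <- scan(path, what = numeric(), quiet = TRUE)
  if (any(v < 0)) stop(sprintf("negative b-value in %s", path))
  v
}

#' @rdname gradient_tables
#' @export
read_bvec <- function(path) {
  rows <- readLines(path)
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) != 3L) stop(sprintf("%s must have exactly 3 rows", path))
  parsed <- lapply(rows, function(r) scan(text = r, what = numeric(),
                                          quiet = TRUE))
  if (length(unique(lengths(parsed))) != 1L)
    stop(sprintf("ragged rows in %s", path))
  do.call(rbind, parsed)
}

#' @rdname gradient_tables
#' @param bval,bvec values to write.
#' @export
write_bval <- function(bval, path) {
  writeLines(paste(format(bval, trim = TRUE, scientific = FALSE),
                   collapse = " "), path)
  invisible(path)
}

#' @rdname gradient_tables
#' @export
write_bvec <- function(bvec, path) {
  writeLines(apply(bvec, 1, function(r)
    paste(formatC(r, format = "f", digits = 8), collapse = " ")), path)
  invisible(path)
}

# ---- NIfTI series ----------------------------------------------------------

#' Read a DWI series from NIfTI + gradient table
#'
#' @param nifti path to a NIfTI-1 4D volume.
#' @param bval,bvec paths to the FSL-style gradient table; defaults replace
#'   the NIfTI extension with `.bval` / `.bvec`.
#' @param waveform,phase quadrant tag (not stored in NIfTI).
#' @return A [dwi_series()].
#' @export
read_series <- function(nifti, bval = NULL, bvec = NULL,
                        waveform = "bipolar", phase = "diastole") {
  stem <- sub("\\.nii(\\.gz)?$", "", nifti)
  if (is.null(bval)) bval <- paste0(stem, ".bval")
  if (is.null(bvec)) bvec <- paste0(stem, ".bvec")
  img <- RNifti::readNifti(nifti)
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  b <- read_bval(bval)
  g <- read_bvec(bvec)
  if (length(b) != dim(arr)[4])
    stop(sprintf("%s: %d volumes but %s lists %d b-values",
                 nifti, dim(arr)[4], bval, length(b)))
  if (ncol(g) != length(b))
    stop(sprintf("%s: %d b-values but %s has %d columns", bval, length(b),
                 bvec, ncol(g)))
  nz <- b > 0
  if (any(abs(sqrt(colSums(g[, nz, drop = FALSE]^2)) - 1) > 1e-6))
    stop(sprintf("%s: non-unit direction at nonzero b", bvec))
  vox <- tryCatch(RNifti::pixdim(img)[1:3], error = function(e) c(1, 1, 1))
  dwi_series(arr, acq_scheme(b, g, waveform, phase), voxdim = vox)
}

#' Write a DWI series as NIfTI + gradient table
#'
#' Signals are stored as float32; `read_series(write_series(x))` preserves
#' the scheme exactly and signals to float32 precision.
#'
#' @param series a [dwi_series()].
#' @param nifti output path (`.nii` or `.nii.gz`).
#' @inheritParams read_series
#' @export
write_series <- function(series, nifti, bval = NULL, bvec = NULL) {
  stopifnot(inherits(series, "dwi_series"))
  stem <- sub("\\.nii(\\.gz)?$", "", nifti)
  if (is.null(bval)) bval <- paste0(stem, ".bval")
  if (is.null(bvec)) bvec <- paste0(stem, ".bvec")
  img <- RNifti::asNifti(series$signal, internal = FALSE)
  RNifti::pixdim(img) <- c(series$voxdim, 1)
  RNifti::writeNifti(img, nifti, datatype = "float")
  write_bval(series$scheme$bval, bval)
  write_bvec(series$scheme$bvec, bvec)
  invisible(c(nifti = nifti, bval = bval, bvec = bvec))
}

#' Read / write a 3D mask volume
#' @param path NIfTI path.
#' @name mask_io
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) > 0.5, dim(img)[1:3])
}

#' @rdname mask_io
#' @param mask logical 3D array.
#' @export
write_mask <- function(mask, path) {
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask), dim(mask)),
                                     datatype = "uint8"), path)
  invisible(path)
}

# ---- subject table ---------------------------------------------------------

.subject_cols <- c("subject_id", "side", "volume_ml", "eGFR", "mGFR",
                   "mGFRt", "SRF", "proteinuria")

#' Read a per-kidney subject table
#'
#' Tab-separated, one row per kidney, with header columns `subject_id`,
#' `side` (L/R), `volume_ml`, `eGFR`, `mGFR`, `mGFRt`, `SRF`,
#' `proteinuria` (0/1). For every subject contributing both kidneys the two
#' SRF values must sum to 1 (within 1e-6); GFR columns may be NA for
#' subjects without the corresponding measurement.
#'
#' @param path TSV path.
#' @return data.frame of typed per-kidney records.
#' @export
read_subject_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(.subject_cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")))
  df$side <- as.character(df$side)
  if (!all(df$side %in% c("L", "R"))) stop("side must be 'L' or 'R'")
  for (col in c("volume_ml", "eGFR", "mGFR", "mGFRt", "SRF"))
    df[[col]] <- as.numeric(df[[col]])
  df$proteinuria <- as.integer(df$proteinuria)
  if (any(!is.na(df$volume_ml) & df$volume_ml <= 0))
    stop("kidney volumes must be > 0")
  validate_srf(df)
  df
}

#' @keywords internal
validate_srf <- function(df, tol = 1e-6) {
  for (id in unique(df$subject_id)) {
    srf <- df$SRF[df$subject_id == id]
    if (any(is.na(srf))) next
    if (any(srf < 0 | srf > 1)) stop(sprintf("subject %s: SRF outside [0,1]", id))
    if (length(srf) == 2L && abs(sum(srf) - 1) > tol)
      stop(sprintf("subject %s: SRF pair sums to %.6f, not 1", id, sum(srf)))
  }
  invisible(TRUE)
}

#' Write a per-kidney subject table
#' @param df data.frame with the columns of [read_subject_table()].
#' @param path output TSV path.
#' @export
write_subject_table <- function(df, path) {
  missing <- setdiff(.subject_cols, names(df))
  if (length(missing))
    stop(sprintf("missing column(s) %s", paste(missing, collapse = ", ")))
  utils::write.table(df[, union(.subject_cols, names(df))], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- YAML run configuration ------------------------------------------------

#' Read / write a run configuration as YAML
#'
#' Configurations (phantom, cohort, fitting options) are plain named lists;
#' the YAML dump written next to run outputs makes a run reproducible.
#'
#' @param x named list.
#' @param path YAML path.
#' @name config_io
#' @export
write_config <- function(x, path) {
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname config_io
#' @export
read_config <- function(path) yaml::read_yaml(path)
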