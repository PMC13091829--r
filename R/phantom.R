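#' Default per-tissue, per-quadrant ground-truth parameter distributions
#'
#' Means and SDs for the synthetic kidney phantom, one row per tissue
#' (cortex, medulla) x quadrant (waveform x cardiac phase). Diffusivities
#' are in um^2/ms. The quadrant contrast encodes the physiology the
#' four-quadrant protocol is designed to separate: flow compensation
#' suppresses the perfusion fraction (nulling slow coherent-flow
#' attenuation), systolic triggering elevates the fast vascular
#' pseudodiffusion terms, and diastolic bipolar encoding retains slow
#' tubular flow.
#'
#' @return data.frame with columns `tissue`, `waveform`, `phase`, `s0_mean`,
#'   `s0_sd`, `md_mean`, `md_sd`, `fa_mean`, `fa_sd`, `fp_mean`, `fp_sd`,
#'   `dp_mean`, `dp_sd`, `dp_ratio` (axial:radial pseudodiffusion eigenvalue
#'   ratio).
#' @export
default_tissue_params <- function() {
  df <- rbind(
    data.frame(tissue = "cortex",  waveform = "bipolar",          phase = "diastole",
               md_mean = 1.95, md_sd = 0.10, fa_mean = 0.19, fa_sd = 0.07,
               fp_mean = 0.16, fp_sd = 0.04, dp_mean = 25.40, dp_sd = 10.28),
    data.frame(tissue = "cortex",  waveform = "bipolar",          phase = "systole",
               md_mean = 2.06, md_sd = 0.21, fa_mean = 0.21, fa_sd = 0.05,
               fp_mean = 0.21, fp_sd = 0.07, dp_mean = 28.95, dp_sd = 15.36),
    data.frame(tissue = "cortex",  waveform = "flow_compensated", phase = "diastole",
               md_mean = 1.91, md_sd = 0.08, fa_mean = 0.10, fa_sd = 0.03,
               fp_mean = 0.08, fp_sd = 0.02, dp_mean = 34.25, dp_sd = 18.76),
    data.frame(tissue = "cortex",  waveform = "flow_compensated", phase = "systole",
               md_mean = 2.03, md_sd = 0.10, fa_mean = 0.13, fa_sd = 0.03,
               fp_mean = 0.11, fp_sd = 0.04, dp_mean = 31.74, dp_sd = 18.14),
    data.frame(tissue = "medulla", waveform = "bipolar",          phase = "diastole",
               md_mean = 1.88, md_sd = 0.11, fa_mean = 0.28, fa_sd = 0.06,
               fp_mean = 0.20, fp_sd = 0.05, dp_mean = 50.89, dp_sd = 20.26),
    data.frame(tissue = "medulla", waveform = "bipolar",          phase = "systole",
               md_mean = 1.95, md_sd = 0.22, fa_mean = 0.29, fa_sd = 0.05,
               fp_mean = 0.21, fp_sd = 0.06, dp_mean = 57.27, dp_sd = 27.84),
    data.frame(tissue = "medulla", waveform = "flow_compensated", phase = "diastole",
               md_mean = 1.80, md_sd = 0.08, fa_mean = 0.16, fa_sd = 0.05,
               fp_mean = 0.10, fp_sd = 0.03, dp_mean = 40.05, dp_sd = 22.10),
    data.frame(tissue = "medulla", waveform = "flow_compensated", phase = "systole",
               md_mean = 1.89, md_sd = 0.09, fa_mean = 0.18, fa_sd = 0.04,
               fp_mean = 0.11, fp_sd = 0.04, dp_mean = 50.11, dp_sd = 24.00))
  df$s0_mean <- 1000
  df$s0_sd <- 50
  df$dp_ratio <- ifelse(df$tissue == "medulla", 2, 1)
  df
}

#' Axially symmetric tensor eigenvalues from MD and FA
#'
#' For a prolate axisymmetric tensor (`l2 = l3`),
#' `l1 = MD (1 + 2 delta)`, `l2 = l3 = MD (1 - delta)` with
#' `delta = FA / sqrt(3 - 2 FA^2)`; this inverts the FA formula exactly, so
#' generated tensors hit a configured (MD, FA) pair by construction.
#'
#' @param md mean diffusivity (um^2/ms).
#' @param fa fractional anisotropy in `[0, 1)`.
#' @return matrix with columns `l1`, `l2`, `l3`.
#' @export
eigenvalues_from_md_fa <- function(md, fa) {
  delta <- fa / sqrt(3 - 2 * fa^2)
  cbind(l1 = md * (1 + 2 * delta), l2 = md * (1 - delta), l3 = md * (1 - delta))
}

#' Phantom configuration
#'
#' Geometry and ground-truth distributions for the synthetic kidney phantom:
#' an ellipsoidal kidney on a regular grid with an outer cortical strip,
#' medullary pyramids whose principal axis points radially at the central
#' pelvis, a central pelvis labelled as excluded (never parenchyma), and an
#' optional spherical lesion, also excluded.
#'
#' @param grid integer grid shape (3 values).
#' @param cortex_thickness cortical strip thickness as a fraction of the
#'   ellipsoid radius, in (0, 1).
#' @param n_pyramids number of medullary pyramids.
#' @param pyramid_halfangle pyramid angular half-width, degrees.
#' @param pelvis_radius pelvis radius as a fraction of the ellipsoid radius.
#' @param lesion_radius optional excluded spherical lesion radius (fraction
#'   of the ellipsoid radius; 0 disables it).
#' @param tissue_params per-tissue, per-quadrant distribution table; see
#'   [default_tissue_params()].
#' @param sigma default Rician noise SD in absolute signal units (used by
#'   [synthesize_dwi()] when not overridden).
#' @param seed integer; fixes all randomness of [make_phantom()].
#' @return list of class `phantom_config`.
#' @export
phantom_config <- function(grid = c(36, 36, 12), cortex_thickness = 0.22,
                           n_pyramids = 6, pyramid_halfangle = 28,
                           pelvis_radius = 0.28, lesion_radius = 0,
                           tissue_params = default_tissue_params(),
                           sigma = 0, seed = 1L) {
  grid <- as.integer(grid)
  if (length(grid) != 3L || any(grid < 6L)) stop("grid must be 3 values >= 6")
  if (cortex_thickness <= 0 || cortex_thickness >= 1)
    stop("cortex_thickness must be in (0, 1)")
  if (pelvis_radius < 0 || pelvis_radius >= 1 - cortex_thickness)
    stop("pelvis must fit inside the medullary region (pelvis_radius < 1 - cortex_thickness)")
  if (n_pyramids < 1) stop("need at least one pyramid")
  needed <- c("tissue", "waveform", "phase", "s0_mean", "s0_sd", "md_mean",
              "md_sd", "fa_mean", "fa_sd", "fp_mean", "fp_sd", "dp_mean",
              "dp_sd", "dp_ratio")
  if (!all(needed %in% names(tissue_params)))
    stop("tissue_params is missing required columns")
  if (any(tissue_params$md_mean <= 0) || any(tissue_params$dp_mean <= 0))
    stop("diffusivity means must be > 0")
  if (any(tissue_params$fp_mean < 0 | tissue_params$fp_mean > 1))
    stop("fp means must lie in [0, 1]")
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(grid = grid, cortex_thickness = cortex_thickness,
                 n_pyramids = n_pyramids,
                 pyramid_halfangle = pyramid_halfangle,
                 pelvis_radius = pelvis_radius, lesion_radius = lesion_radius,
                 tissue_params = tissue_params, sigma = sigma,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# deterministic orthonormal completion of a unit vector
.complete_frame <- function(e1) {
  a <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- a - sum(a * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  cbind(e1, e2, e3, deparse.level = 0)
}

.tp_key <- function(tissue, waveform, phase) paste(tissue, waveform, phase, sep = "|")

#' Generate ground-truth parameter maps for the kidney phantom
#'
#' Builds the label geometry (cortex strip / medullary pyramids / excluded
#' pelvis and optional lesion), assigns a structural eigenframe per voxel
#' (medulla: principal axis radial, pointing at the pelvis; cortex: random
#' orientation), and draws voxel-wise (S0, tensor eigenvalues, fp,
#' pseudodiffusion eigenvalues) per quadrant from the configured
#' distributions. Tensors are axisymmetric with eigenvalues derived from
#' (MD, FA) draws, so tissue-mean MD and FA match the configured targets by
#' construction. Pseudodiffusion eigenvalues share the structural
#' eigenvectors and are clipped, if necessary, to exceed the largest
#' structural eigenvalue.
#'
#' @param config a [phantom_config()].
#' @return list of class `ground_truth_maps` with `labels` (0 background,
#'   1 cortex, 2 medulla, 3 excluded), `masks` (a [mask_set()]), `evec`
#'   (array `c(grid, 3, 3)`; `evec[x,y,z,,i]` is eigenvector i), and per
#'   quadrant (named `waveform_phase`) the arrays `s0`, `lambda`
#'   (`c(grid, 3)`), `fp`, `lambda_p` (`c(grid, 3)`), plus `config`.
#' @export
make_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  g <- config$grid
  ctr <- (g + 1) / 2
  semi <- 0.45 * g
  ax <- (seq_len(g[1]) - ctr[1]) / semi[1]
  ay <- (seq_len(g[2]) - ctr[2]) / semi[2]
  az <- (seq_len(g[3]) - ctr[3]) / semi[3]
  X <- array(rep(ax, times = g[2] * g[3]), g)
  Y <- array(rep(rep(ay, each = g[1]), times = g[3]), g)
  Z <- array(rep(az, each = g[1] * g[2]), g)
  rho <- sqrt(X^2 + Y^2 + Z^2)

  kidney <- rho <= 1
  cortex <- kidney & rho > 1 - config$cortex_thickness
  pelvis <- rho < config$pelvis_radius
  interior <- kidney & !cortex & !pelvis

  # pyramid axes: evenly spaced azimuths in the xy plane
  theta <- 2 * pi * (seq_len(config$n_pyramids) - 1) / config$n_pyramids
  axes <- cbind(cos(theta), sin(theta), 0)
  cosw <- cos(config$pyramid_halfangle * pi / 180)
  wx <- X / pmax(rho, 1e-12); wy <- Y / pmax(rho, 1e-12); wz <- Z / pmax(rho, 1e-12)
  best <- array(-1, g)
  for (p in seq_len(config$n_pyramids)) {
    d <- wx * axes[p, 1] + wy * axes[p, 2] + wz * axes[p, 3]
    best <- pmax(best, d)
  }
  medulla <- interior & best >= cosw

  labels <- array(0L, g)
  labels[cortex] <- 1L
  labels[medulla] <- 2L
  labels[pelvis] <- 3L
  if (config$lesion_radius > 0) {
    lct <- ctr + c(0.55, 0, 0) * semi   # lesion seated in the cortical shell
    lr <- config$lesion_radius * mean(semi)
    les <- sqrt((X * semi[1] + ctr[1] - lct[1])^2 +
                (Y * semi[2] + ctr[2] - lct[2])^2 +
                (Z * semi[3] + ctr[3] - lct[3])^2) <= lr
    if (!any(les & kidney))
      stop("configured lesion falls outside the kidney")
    labels[les & kidney] <- 3L
  }
  if (!any(labels == 2L))
    stop("pyramids fall outside the grid interior; enlarge the grid or shrink the pelvis")

  masks <- mask_set(cortex = labels == 1L, medulla = labels == 2L,
                    excluded = labels == 3L)

  # structural eigenframe (shared across quadrants)
  evec <- array(NA_real_, c(g, 3, 3))
  idx_tissue <- which(labels == 1L | labels == 2L)
  n3 <- prod(g)
  arr_ind <- arrayInd(idx_tissue, g)
  for (k in seq_along(idx_tissue)) {
    v <- idx_tissue[k]
    if (labels[v] == 2L) {
      e1 <- c(wx[v], wy[v], wz[v])       # radial: toward/away from the pelvis
    } else {
      e1 <- stats::rnorm(3)
    }
    e1 <- e1 / sqrt(sum(e1^2))
    E <- .complete_frame(e1)
    for (i in 1:3) evec[v + (0:2) * n3 + (i - 1) * 3 * n3] <- E[, i]
  }

  tp <- config$tissue_params
  keys <- .tp_key(tp$tissue, tp$waveform, tp$phase)
  qs <- quadrants()
  out <- list(labels = labels, masks = masks, evec = evec, config = config)
  rtrunc <- function(n, mean, sd, lo, hi = Inf) pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
  for (q in seq_len(nrow(qs))) {
    s0 <- array(NA_real_, g)
    lambda <- array(NA_real_, c(g, 3))
    fp <- array(NA_real_, g)
    lambda_p <- array(NA_real_, c(g, 3))
    for (tis in c("cortex", "medulla")) {
      row <- tp[keys == .tp_key(tis, qs$waveform[q], qs$phase[q]), ]
      if (nrow(row) != 1L)
        stop(sprintf("tissue_params must have exactly one row for %s/%s/%s",
                     tis, qs$waveform[q], qs$phase[q]))
      vox <- which(labels == (if (tis == "cortex") 1L else 2L))
      n <- length(vox)
      md <- rtrunc(n, row$md_mean, row$md_sd, 0.2)
      fa <- rtrunc(n, row$fa_mean, row$fa_sd, 0.01, 0.9)
      lam <- eigenvalues_from_md_fa(md, fa)
      dp <- rtrunc(n, row$dp_mean, row$dp_sd, 3)
      r <- row$dp_ratio
      lamp <- cbind(dp * 3 * r / (r + 2), dp * 3 / (r + 2), dp * 3 / (r + 2))
      # invariant: every pseudodiffusion eigenvalue exceeds the largest
      # structural eigenvalue
      lamp <- pmax(lamp, 1.05 * lam[, 1])
      s0[vox] <- rtrunc(n, row$s0_mean, row$s0_sd, 1)
      fp[vox] <- rtrunc(n, row$fp_mean, row$fp_sd, 0, 1)
      for (i in 1:3) {
        lambda[vox + (i - 1) * n3] <- lam[, i]
        lambda_p[vox + (i - 1) * n3] <- lamp[, i]
      }
    }
    out[[qs$quadrant[q]]] <- list(s0 = s0, lambda = lambda, fp = fp,
                                  lambda_p = lambda_p,
                                  waveform = qs$waveform[q], phase = qs$phase[q])
  }
  class(out) <- "ground_truth_maps"
  out
}

#' @export
print.ground_truth_maps <- function(x, ...) {
  cat(sprintf("<ground_truth_maps> grid %s: %d cortex, %d medulla, %d excluded voxels\n",
              paste(dim(x$labels), collapse = "x"), sum(x$labels == 1L),
              sum(x$labels == 2L), sum(x$labels == 3L)))
  invisible(x)
}

#' Synthesize a DWI series from ground-truth maps
#'
#' Evaluates the biexponential model per voxel and direction,
#' `S = S0 (fp e^(-b g'Dp g) + (1 - fp) e^(-b g'Dt g))`, with the
#' direction-dependent diffusivities `g' D g = sum_i lambda_i (g . e_i)^2`,
#' then applies Rician noise (`sqrt((S + sigma N1)^2 + (sigma N2)^2)`) when
#' `sigma > 0` — magnitude MRI noise, while the fitters assume Gaussian
#' residuals, as is standard. The noiseless signal at b = 0 equals S0
#' exactly. Background voxels have zero noiseless signal (pure Rayleigh
#' noise when sigma > 0).
#'
#' @param maps a [make_phantom()] result.
#' @param scheme an [acq_scheme()]; its waveform/phase selects the quadrant.
#' @param sigma Rician noise SD (absolute signal units); defaults to the
#'   phantom config value.
#' @param seed noise seed; defaults to the phantom seed + 1.
#' @return A [dwi_series()] with the phantom `mask_set` attached.
#' @export
synthesize_dwi <- function(maps, scheme, sigma = NULL, seed = NULL) {
  stopifnot(inherits(maps, "ground_truth_maps"), inherits(scheme, "acq_scheme"))
  if (is.null(sigma)) sigma <- maps$config$sigma
  if (sigma < 0) stop("sigma must be >= 0")
  if (is.null(seed)) seed <- maps$config$seed + 1L
  qname <- paste(scheme$waveform, scheme$phase, sep = "_")
  qd <- maps[[qname]]
  if (is.null(qd)) stop(sprintf("phantom has no quadrant %s", qname))
  g <- dim(maps$labels)
  n3 <- prod(g)
  vox <- which(maps$labels == 1L | maps$labels == 2L | maps$labels == 3L)
  # excluded voxels get cortex-like signal so that lesions/pelvis are not
  # trivially background; draw from the quadrant's cortex-as-fallback values
  filled <- vox[!is.na(qd$s0[vox])]
  nvox <- length(filled)
  lam <- matrix(qd$lambda[rep(filled, 3) + rep((0:2) * n3, each = nvox)], nvox, 3)
  lamp <- matrix(qd$lambda_p[rep(filled, 3) + rep((0:2) * n3, each = nvox)], nvox, 3)
  E <- array(NA_real_, c(nvox, 3, 3))
  for (i in 1:3) for (cmp in 1:3)
    E[, cmp, i] <- maps$evec[filled + (cmp - 1) * n3 + (i - 1) * 3 * n3]
  s0 <- qd$s0[filled]
  fpv <- qd$fp[filled]

  nvol <- length(scheme$bval)
  b <- b_si(scheme$bval)
  sig <- array(0, c(g, nvol))
  for (j in seq_len(nvol)) {
    if (b[j] == 0) {
      sv <- s0
    } else {
      gj <- scheme$bvec[, j]
      dt_g <- numeric(nvox); dp_g <- numeric(nvox)
      for (i in 1:3) {
        ci <- (E[, 1, i] * gj[1] + E[, 2, i] * gj[2] + E[, 3, i] * gj[3])^2
        dt_g <- dt_g + lam[, i] * ci
        dp_g <- dp_g + lamp[, i] * ci
      }
      sv <- s0 * (fpv * exp(-b[j] * dp_g) + (1 - fpv) * exp(-b[j] * dt_g))
    }
    sig[filled + (j - 1) * n3] <- sv
  }
  if (sigma > 0) {
    set.seed(seed)
    n1 <- array(stats::rnorm(n3 * nvol, 0, sigma), c(g, nvol))
    n2 <- array(stats::rnorm(n3 * nvol, 0, sigma), c(g, nvol))
    sig <- sqrt((sig + n1)^2 + n2^2)
  }
  dwi_series(sig, scheme, masks = maps$masks)
}
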