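#' Fixed 12-direction diffusion gradient set
#'
#' Unit gradient directions obtained once by electrostatic-repulsion
#' minimisation on the half-sphere (antipodally symmetric pair energy) and
#' frozen as a constant. The 6-component tensor design built from these
#' directions has condition number 1.60, comfortably above the minimal
#' 6-direction requirement for tensor estimation.
#'
#' @format A 12 x 3 numeric matrix of unit row vectors (image coordinates).
#' @export
refmap_directions <- matrix(c(
   0.15110960,  0.30401854,  0.94060545,
  -0.26844403, -0.27744796,  0.92247517,
  -0.65345801,  0.26367865,  0.70955352,
   0.22337525, -0.67084163,  0.70715982,
   0.70133757, -0.13609523,  0.69971687,
  -0.30748341,  0.82608804,  0.47226317,
   0.38907372,  0.79149528,  0.47133519,
  -0.73270849, -0.52386171,  0.43440439,
   0.88089218,  0.39810092,  0.25601686,
  -0.18248173, -0.96397703,  0.19351666,
   0.62967133, -0.76267173,  0.14780342,
  -0.97564683,  0.20026307,  0.08948719),
  ncol = 3, byrow = TRUE)
refmap_directions <- refmap_directions /
  sqrt(rowSums(refmap_directions^2))

#' b-value menu of the four-quadrant renal protocol (s/mm^2)
#' @export
refmap_bvalues <- c(0, 10, 30, 50, 70, 80, 100, 120, 200, 400, 600, 800)

.quadrant_waveforms <- c("bipolar", "flow_compensated")
.quadrant_phases <- c("diastole", "systole")

#' Enumerate the four acquisition quadrants
#'
#' The protocol crosses two diffusion gradient waveforms (bipolar, which
#' retains slow coherent-flow attenuation, and flow-compensated, which nulls
#' it) with two cardiac trigger phases (systole: peak renal inflow;
#' diastole: minimal inflow).
#'
#' @return data.frame with columns `waveform`, `phase` and a `quadrant` label.
#' @export
quadrants <- function() {
  g <- expand.grid(phase = .quadrant_phases, waveform = .quadrant_waveforms,
                   stringsAsFactors = FALSE)[, c("waveform", "phase")]
  g$quadrant <- paste(g$waveform, g$phase, sep = "_")
  g
}

#' Construct an acquisition scheme
#'
#' Binds per-volume b-values and gradient directions to a quadrant tag.
#' b-values are stored in s/mm^2 (the unit on scanner consoles and in
#' `.bval` files); fitting routines convert to ms/um^-2 so that b*D is
#' dimensionless with diffusivities in um^2/ms.
#'
#' @param bval numeric vector of b-values in s/mm^2, one per volume.
#' @param bvec 3 x nvol (or nvol x 3) matrix of gradient directions; rows or
#'   columns for nonzero b must be unit vectors, b=0 entries are arbitrary
#'   (conventionally zero).
#' @param waveform `"bipolar"` or `"flow_compensated"`.
#' @param phase `"systole"` or `"diastole"`.
#' @return An object of class `acq_scheme`.
#' @export
acq_scheme <- function(bval, bvec, waveform = "bipolar", phase = "diastole") {
  bval <- as.numeric(bval)
  if (any(!is.finite(bval)) || any(bval < 0))
    stop("b-values must be finite and >= 0")
  if (!any(bval == 0))
    stop("scheme must contain at least one b=0 volume")
  bvec <- as.matrix(bvec)
  if (ncol(bvec) == 3L && nrow(bvec) != 3L) bvec <- t(bvec)
  if (nrow(bvec) != 3L || ncol(bvec) != length(bval))
    stop("bvec must be 3 x nvol matching length(bval)")
  nz <- bval > 0
  nrm <- sqrt(colSums(bvec[, nz, drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("gradient directions at nonzero b must be unit-norm (within 1e-6)")
  waveform <- match.arg(waveform, .quadrant_waveforms)
  phase <- match.arg(phase, .quadrant_phases)
  structure(list(bval = bval, bvec = bvec, waveform = waveform, phase = phase),
            class = "acq_scheme")
}

#' Study-emulating scheme: 11 nonzero shells x 12 directions + one b=0
#'
#' One b=0 volume followed by all 12 directions at each nonzero b-value
#' (133 volumes).
#'
#' @inheritParams acq_scheme
#' @param bvalues b-value menu in s/mm^2.
#' @param directions matrix of unit directions (rows).
#' @export
study_scheme <- function(waveform = "bipolar", phase = "diastole",
                         bvalues = refmap_bvalues,
                         directions = refmap_directions) {
  bnz <- sort(unique(bvalues[bvalues > 0]))
  ndir <- nrow(directions)
  bval <- c(0, rep(bnz, each = ndir))
  bvec <- cbind(c(0, 0, 0),
                t(directions[rep(seq_len(ndir), times = length(bnz)), ]))
  acq_scheme(bval, bvec, waveform = waveform, phase = phase)
}

#' @export
print.acq_scheme <- function(x, ...) {
  cat(sprintf("<acq_scheme> %s / %s: %d volumes, b in {%s} s/mm^2\n",
              x$waveform, x$phase, length(x$bval),
              paste(sort(unique(x$bval)), collapse = ", ")))
  invisible(x)
}

# b conversion: s/mm^2 -> ms/um^2 so that b*D is dimensionless for D in
# um^2/ms (800 s/mm^2 <-> 0.8).
b_si <- function(bval_s_mm2) bval_s_mm2 / 1000
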