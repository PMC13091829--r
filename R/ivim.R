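#' Biexponential IVIM signal model
#'
#' Signal for the intravoxel incoherent motion model
#' `S(b) = S0 * (fp * exp(-b * Dp) + (1 - fp) * exp(-b * Dt))`,
#' with `b` in ms/um^2 and diffusivities in um^2/ms so that `b * D` is
#' dimensionless (b = 800 s/mm^2 corresponds to `b = 0.8` here).
#'
#' @param b diffusion weighting in ms/um^2 (vectorised).
#' @param S0 signal at b = 0 (> 0).
#' @param fp perfusion fraction in `[0, 1]`.
#' @param Dt tissue diffusivity in um^2/ms (> 0).
#' @param Dp pseudodiffusivity in um^2/ms (>= Dt for a meaningful fit).
#' @return Signal values, same length as `b`.
#' @export
ivim_signal <- function(b, S0, fp, Dt, Dp) {
  if (any(b < 0)) stop("b must be >= 0")
  if (S0 <= 0) stop("S0 must be > 0")
  if (fp < 0 || fp > 1) stop("fp must lie in [0, 1]")
  if (Dt <= 0) stop("Dt must be > 0")
  S0 * (fp * exp(-b * Dp) + (1 - fp) * exp(-b * Dt))
}

#' Stage 1 of the segmented IVIM fit: high-b monoexponential regression
#'
#' Ordinary least squares of `log(S)` on `b` restricted to b-values above the
#' perfusion cutoff (default 200 s/mm^2, where the pseudodiffusion term has
#' decayed away). The negative slope estimates the tissue diffusivity `Dt`;
#' extrapolating the intercept back to b = 0 and comparing with the measured
#' b = 0 signal gives a first perfusion-fraction estimate
#' `fp_init = 1 - exp(intercept) / S0`.
#'
#' @param signal signal vector, one value per volume.
#' @param bval b-values in s/mm^2, same length.
#' @param b_threshold perfusion cutoff in s/mm^2; volumes with
#'   `bval > b_threshold` enter the regression.
#' @return list with `Dt`, `fp_init`, `s0_extrapolated`, `s0_measured`,
#'   `residual` (stage-1 RMS on log-signal), `clipped` (was `fp_init`
#'   clipped into `[0,1]`), and `ok`.
#' @export
fit_ivim_stage1 <- function(signal, bval, b_threshold = 200) {
  stopifnot(length(signal) == length(bval))
  if (!any(bval == 0)) stop("scheme has no b=0 measurement")
  hi <- bval > b_threshold
  if (length(unique(bval[hi])) < 2L)
    stop(sprintf("need >= 2 distinct b-values above %g s/mm^2", b_threshold))
  s0_measured <- mean(signal[bval == 0])
  s_hi <- signal[hi]
  if (any(s_hi <= 0) || s0_measured <= 0)
    return(list(ok = FALSE, status = "failed"))
  b <- b_si(bval[hi])
  fit <- stats::lm.fit(cbind(1, -b), log(s_hi))
  dt <- fit$coefficients[[2]]
  s0_extrap <- exp(fit$coefficients[[1]])
  fp_raw <- 1 - s0_extrap / s0_measured
  list(ok = TRUE, status = "ok",
       Dt = dt, fp_init = min(max(fp_raw, 0), 1),
       s0_extrapolated = s0_extrap, s0_measured = s0_measured,
       residual = sqrt(mean(fit$residuals^2)),
       clipped = (fp_raw < 0 || fp_raw > 1))
}

#' Stage 2 of the segmented IVIM fit: constrained biexponential fit
#'
#' Bounded nonlinear least squares of the biexponential model over
#' `(fp, Dp)` on all b-values, with `Dt` frozen at the stage-1 estimate and
#' `S0` fixed to the measured b = 0 mean (avoiding the 3-parameter
#' degeneracy at low perfusion fractions). Three pseudodiffusivity starts
#' (`5 Dt`, `10 Dt`, `50 Dt`) guard against local minima; the lowest SSE
#' wins, ties going to the smaller `Dp`.
#'
#' @inheritParams fit_ivim_stage1
#' @param Dt_fixed stage-1 tissue diffusivity (um^2/ms).
#' @param fp_init stage-1 perfusion fraction start.
#' @param S0 fixed b = 0 signal; default the measured b = 0 mean.
#' @param dp_max upper pseudodiffusivity bound (um^2/ms).
#' @param fp_floor perfusion fractions below this are reported as
#'   `dp_undefined` (the pseudodiffusivity is unidentifiable).
#' @return list with `fp`, `Dp`, `sse`, `status`.
#' @export
fit_ivim_stage2 <- function(signal, bval, Dt_fixed, fp_init,
                            S0 = NULL, dp_max = 500, fp_floor = 0.01) {
  stopifnot(length(signal) == length(bval))
  if (is.null(S0)) S0 <- mean(signal[bval == 0])
  if (!is.finite(Dt_fixed) || Dt_fixed <= 0 || S0 <= 0)
    return(list(status = "failed"))
  b <- b_si(bval)
  e_t <- exp(-b * Dt_fixed)
  sse <- function(par) {
    pred <- S0 * (par[1] * exp(-b * par[2]) + (1 - par[1]) * e_t)
    sum((signal - pred)^2)
  }
  lower <- c(0, Dt_fixed)
  upper <- c(1, dp_max)
  fp0 <- min(max(fp_init, 1e-3), 0.999)
  starts <- lapply(pmin(c(5, 10, 50) * Dt_fixed, dp_max),
                   function(dp0) c(fp0, dp0))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, sse, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-12 ||
        (abs(fit$value - best$value) <= 1e-12 && fit$par[2] < best$par[2]))
      best <- fit
  }
  if (is.null(best)) return(list(status = "failed"))
  fp <- best$par[1]; dp <- best$par[2]
  status <- if (fp < fp_floor) "dp_undefined" else "ok"
  list(fp = fp, Dp = dp, sse = best$value, status = status)
}

#' Segmented biexponential IVIM fit for one voxel
#'
#' Runs the two-stage fit: high-b monoexponential regression for `Dt`
#' ([fit_ivim_stage1()]), then the constrained biexponential fit for
#' `(fp, Dp)` on all b-values ([fit_ivim_stage2()]).
#'
#' @inheritParams fit_ivim_stage1
#' @inheritParams fit_ivim_stage2
#' @return list with `S0`, `Dt`, `fp`, `Dp`, `stage1_residual`, `sse`,
#'   `status` in `{"ok", "fp_floor", "dp_undefined", "failed"}`.
#' @export
fit_ivim_voxel <- function(signal, bval, b_threshold = 200, dp_max = 500,
                           fp_floor = 0.01) {
  s1 <- fit_ivim_stage1(signal, bval, b_threshold)
  if (!s1$ok)
    return(list(S0 = NA_real_, Dt = NA_real_, fp = NA_real_, Dp = NA_real_,
                stage1_residual = NA_real_, sse = NA_real_, status = "failed"))
  s2 <- fit_ivim_stage2(signal, bval, s1$Dt, s1$fp_init,
                        S0 = s1$s0_measured, dp_max = dp_max,
                        fp_floor = fp_floor)
  if (identical(s2$status, "failed"))
    return(list(S0 = s1$s0_measured, Dt = s1$Dt, fp = NA_real_,
                Dp = NA_real_, stage1_residual = s1$residual,
                sse = NA_real_, status = "failed"))
  status <- s2$status
  if (status == "ok" && isTRUE(s1$clipped)) status <- "fp_floor"
  list(S0 = s1$s0_measured, Dt = s1$Dt, fp = s2$fp,
       Dp = if (s2$status == "dp_undefined") NA_real_ else s2$Dp,
       stage1_residual = s1$residual, sse = s2$sse, status = status)
}

#' Average a DWI series over directions
#'
#' Arithmetic mean of all volumes sharing a b-value, the input to the
#' direction-averaged IVIM fit.
#'
#' @param series a [dwi_series()].
#' @return list with `signal` (4D array, one volume per unique b) and
#'   `bval` (unique b-values, s/mm^2, ascending).
#' @export
direction_average <- function(series) {
  stopifnot(inherits(series, "dwi_series"))
  ub <- sort(unique(series$scheme$bval))
  d <- dim(series$signal)
  out <- array(0, c(d[1:3], length(ub)))
  for (i in seq_along(ub)) {
    idx <- which(series$scheme$bval == ub[i])
    sub <- series$signal[, , , idx, drop = FALSE]
    out[, , , i] <- apply(sub, 1:3, mean)
  }
  list(signal = out, bval = ub)
}

#' Voxel-wise direction-averaged IVIM maps
#'
#' Direction-averages the series, then applies the segmented biexponential
#' fit voxel by voxel inside the mask. Voxel failures are recorded in the
#' status map, never fatal.
#'
#' @param series a [dwi_series()].
#' @param mask logical 3D array selecting voxels to fit.
#' @inheritParams fit_ivim_voxel
#' @return list of 3D maps `S0`, `Dt`, `fp`, `Dp` (NA outside mask or on
#'   failure) and a character `status` map.
#' @export
fit_ivim <- function(series, mask, b_threshold = 200, dp_max = 500,
                     fp_floor = 0.01) {
  stopifnot(inherits(series, "dwi_series"))
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(mask), dim(series$signal)[1:3]))
    stop("mask grid does not match the series")
  if (!any(mask)) stop("mask is empty")
  avg <- direction_average(series)
  dims <- dim(mask)
  maps <- list(S0 = array(NA_real_, dims), Dt = array(NA_real_, dims),
               fp = array(NA_real_, dims), Dp = array(NA_real_, dims))
  status <- array(NA_character_, dims)
  idx <- which(mask)
  nvol <- length(avg$bval)
  sig_mat <- matrix(avg$signal, prod(dims), nvol)[idx, , drop = FALSE]
  for (k in seq_along(idx)) {
    fit <- fit_ivim_voxel(sig_mat[k, ], avg$bval, b_threshold = b_threshold,
                          dp_max = dp_max, fp_floor = fp_floor)
    maps$S0[idx[k]] <- fit$S0
    maps$Dt[idx[k]] <- fit$Dt
    maps$fp[idx[k]] <- fit$fp
    maps$Dp[idx[k]] <- fit$Dp
    status[idx[k]] <- fit$status
  }
  c(maps, list(status = status))
}
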