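#' Mixed-effects LASSO regression with subject-grouped cross-validation
#'
#' L1-penalised fixed effects with a subject random intercept, for
#' multiparameter prediction of kidney function from per-kidney metric
#' panels where each subject contributes two kidneys. The penalised
#' coordinate-descent step is solved by glmnet on internally standardised
#' predictors; between steps the subject random intercepts are re-estimated:
#' variance components (sigma_u^2, sigma_e^2) by one-way ANOVA moments on
#' the current residuals, then BLUP shrinkage
#' `b_i = sigma_u^2 / (sigma_u^2 + sigma_e^2 / n_i) * mean residual_i`,
#' and the lasso is refit on `y - b`. The tuning parameter is chosen by
#' K-fold cross-validation grouped by subject (both kidneys of a subject
#' stay in the same fold), minimising held-out Gaussian deviance (mean
#' squared error) of the fixed-effect predictions; held-out subjects are new
#' subjects, so their random intercept is 0.
#'
#' @param X numeric predictor matrix (rows: kidneys; columns: metric x
#'   context panel). Constant columns are dropped with a warning.
#' @param y outcome (split mGFR or mGFRt).
#' @param subject subject identifiers, one per row.
#' @param K number of cross-validation folds (grouped by subject).
#' @param seed seed for the fold assignment.
#' @param lambda optional fixed penalty (skips cross-validation); `Inf`
#'   gives the fully shrunk model (all penalised coefficients 0, intercept
#'   at the outcome grand mean).
#' @param nlambda path length when cross-validating.
#' @param maxit_blup random-intercept re-estimation sweeps per lambda.
#' @return list of class `lasso_mixed` with `coef` (original scale),
#'   `coef_std` (standardised scale), `intercept`, `lambda`, `sigma_u2`,
#'   `sigma_e2`, `r2_marginal` (squared correlation of fixed-effect
#'   predictions with the outcome; the headline value), `r2_conditional`
#'   (including random intercepts), `cv` (per-lambda mean held-out
#'   deviance), `folds`, `selected` (names of nonzero coefficients), `seed`.
#' @export
lasso_mixed <- function(X, y, subject, K = 5, seed = 1L, lambda = NULL,
                        nlambda = 40, maxit_blup = 8) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  ok <- stats::complete.cases(X) & is.finite(y) & !is.na(subject)
  X <- X[ok, , drop = FALSE]; y <- y[ok]; subject <- as.character(subject)[ok]
  n <- nrow(X)
  if (n < 2 * K) stop("too few rows for the requested folds")

  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping constant predictor(s): %s",
                    paste(colnames(X)[sds == 0], collapse = ", ")))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  mus <- colMeans(X)
  Xs <- sweep(sweep(X, 2, mus), 2, sds, "/")

  subj_levels <- unique(subject)
  g <- length(subj_levels)
  si <- match(subject, subj_levels)
  ni <- tabulate(si, g)

  # one penalised fit at a fixed lambda with random-intercept sweeps
  fit_at <- function(Xs, y, si_local, ni_local, lam, sweeps) {
    b <- rep(0, length(unique(si_local)))
    beta <- rep(0, ncol(Xs)); b0 <- mean(y)
    for (it in seq_len(sweeps)) {
      yw <- y - b[si_local]
      if (is.finite(lam)) {
        fit <- glmnet::glmnet(Xs, yw, lambda = lam, standardize = FALSE)
        beta_new <- as.numeric(fit$beta)
        b0_new <- as.numeric(fit$a0)
      } else {
        beta_new <- rep(0, ncol(Xs)); b0_new <- mean(yw)
      }
      resid <- y - b0_new - drop(Xs %*% beta_new)
      vc <- varcomp_local(resid, si_local, ni_local)
      b_new <- vc$sig_u2 / (vc$sig_u2 + vc$sig_e2 / ni_local) * vc$m_i
      conv <- max(abs(beta_new - beta), abs(b0_new - b0)) < 1e-7
      beta <- beta_new; b0 <- b0_new; b <- b_new
      if (conv) break
    }
    list(beta = beta, b0 = b0, b = b, sig_u2 = vc$sig_u2, sig_e2 = vc$sig_e2)
  }
  varcomp_local <- function(resid, si_local, ni_local) {
    gl <- length(ni_local)
    m_i <- as.numeric(tapply(resid, si_local, mean)[as.character(seq_len(gl))])
    ssw <- sum((resid - m_i[si_local])^2)
    dfw <- length(resid) - gl
    sig_e2 <- if (dfw > 0) ssw / dfw else stats::var(resid)
    sig_u2 <- max(0, stats::var(m_i) - sig_e2 * mean(1 / ni_local))
    list(sig_u2 = sig_u2, sig_e2 = max(sig_e2, 1e-12), m_i = m_i)
  }

  cv_tab <- NULL
  folds <- NULL
  if (is.null(lambda)) {
    # lambda path from a first pass ignoring grouping
    path <- glmnet::glmnet(Xs, y, nlambda = nlambda, standardize = FALSE)
    lams <- path$lambda
    set.seed(seed)
    fold_of_subj <- sample(rep(seq_len(K), length.out = g))
    folds <- fold_of_subj[si]
    dev <- matrix(NA_real_, K, length(lams))
    for (k in seq_len(K)) {
      tr <- folds != k
      if (length(unique(si[tr])) < 2) stop("a fold left fewer than 2 subjects")
      si_tr <- match(si[tr], unique(si[tr]))
      ni_tr <- tabulate(si_tr)
      for (l in seq_along(lams)) {
        f <- fit_at(Xs[tr, , drop = FALSE], y[tr], si_tr, ni_tr, lams[l],
                    sweeps = 3)
        pred <- f$b0 + drop(Xs[!tr, , drop = FALSE] %*% f$beta)
        dev[k, l] <- mean((y[!tr] - pred)^2)
      }
    }
    cvm <- colMeans(dev)
    lambda <- lams[which.min(cvm)]
    cv_tab <- data.frame(lambda = lams, cv_deviance = cvm)
  }

  f <- fit_at(Xs, y, si, ni, lambda, sweeps = maxit_blup)
  pred_fix <- f$b0 + drop(Xs %*% f$beta)
  pred_cond <- pred_fix + f$b[si]
  r2m <- if (stats::sd(pred_fix) == 0) 0 else stats::cor(pred_fix, y)^2
  r2c <- if (stats::sd(pred_cond) == 0) 0 else stats::cor(pred_cond, y)^2
  coef_orig <- f$beta / sds
  names(coef_orig) <- names(f$beta) <- colnames(Xs)
  intercept <- f$b0 - sum(coef_orig * mus)
  structure(list(coef = coef_orig, coef_std = f$beta, intercept = intercept,
                 lambda = lambda, sigma_u2 = f$sig_u2, sigma_e2 = f$sig_e2,
                 r2_marginal = r2m, r2_conditional = r2c,
                 cv = cv_tab, folds = folds,
                 selected = colnames(Xs)[f$beta != 0], seed = seed),
            class = "lasso_mixed")
}

#' @export
print.lasso_mixed <- function(x, ...) {
  cat(sprintf("<lasso_mixed> lambda = %.4g, %d/%d nonzero, marginal R2 = %.3f (conditional %.3f)\n",
              x$lambda, length(x$selected), length(x$coef),
              x$r2_marginal, x$r2_conditional))
  invisible(x)
}
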