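# Shared fixtures and independent oracles for the test suite.

# small, fast phantom used across tests
small_phantom_config <- function(seed = 7, ...) {
  phantom_config(grid = c(24, 24, 8), seed = seed, ...)
}

# a sample with exact mean and SD (for reconstructing group tests from
# printed summary statistics)
sample_with_moments <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  z <- as.numeric(scale(stats::rnorm(n)))
  mean + sd * z
}

# mean of a Rician(nu, sigma) variate, closed form via scaled Bessel
# functions: E = sigma sqrt(pi/2) [(1+a) I0(a/2) + a I1(a/2)] e^{-a/2},
# a = nu^2 / (2 sigma^2)
rician_mean <- function(nu, sigma) {
  a <- nu^2 / (2 * sigma^2)
  sigma * sqrt(pi / 2) *
    ((1 + a) * besselI(a / 2, 0, expon.scaled = TRUE) +
       a * besselI(a / 2, 1, expon.scaled = TRUE))
}

# noiseless biexponential signals on the study b-menu
biexp_signal <- function(bval_s_mm2, S0, fp, Dt, Dp) {
  b <- bval_s_mm2 / 1000
  S0 * (fp * exp(-b * Dp) + (1 - fp) * exp(-b * Dt))
}

# bivariate random-intercept cohort with a known total correlation
# (between + within covariance split); returns per-kidney x, y, subject
simulate_bilateral <- function(n_subjects, var_b = c(0.5, 0.5),
                               cov_b = 0.4, var_w = c(0.5, 0.5),
                               cov_w = 0.3, seed = 1) {
  set.seed(seed)
  SB <- matrix(c(var_b[1], cov_b, cov_b, var_b[2]), 2, 2)
  SW <- matrix(c(var_w[1], cov_w, cov_w, var_w[2]), 2, 2)
  LB <- t(chol(SB)); LW <- t(chol(SW))
  a <- t(LB %*% matrix(rnorm(2 * n_subjects), 2))
  e1 <- t(LW %*% matrix(rnorm(2 * n_subjects), 2))
  e2 <- t(LW %*% matrix(rnorm(2 * n_subjects), 2))
  Tm <- SB + SW
  list(x = c(a[, 1] + e1[, 1], a[, 1] + e2[, 1]),
       y = c(a[, 2] + e1[, 2], a[, 2] + e2[, 2]),
       subject = rep(seq_len(n_subjects), 2),
       r_true = Tm[1, 2] / sqrt(Tm[1, 1] * Tm[2, 2]))
}

# grouped design with 3 true predictors among p candidates; true predictors
# pairwise correlated (rho) so each carries univariate r ~ 0.6
simulate_lasso_cohort <- function(n_subjects = 60, p = 24, beta = 1,
                                  rho = 0.5, sigma_u = 1, sigma_e = 1.4,
                                  seed = 1) {
  set.seed(seed)
  n <- 2 * n_subjects
  subject <- rep(seq_len(n_subjects), each = 2)
  z <- rnorm(n)
  X <- matrix(rnorm(n * p), n, p)
  X[, 1:3] <- sqrt(rho) * z + sqrt(1 - rho) * X[, 1:3]
  colnames(X) <- paste0("m", seq_len(p))
  u <- rnorm(n_subjects, 0, sigma_u)
  y <- drop(X[, 1:3] %*% rep(beta, 3)) + u[subject] + rnorm(n, 0, sigma_e)
  list(X = X, y = y, subject = subject)
}
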