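test_that("FA closed forms hold", {
  expect_equal(compute_fa(2, 2, 2), 0)
  expect_equal(compute_fa(1, 0, 0), 1)
  expect_equal(compute_fa(2.44, 1.61, 1.61), 0.2487015, tolerance = 2e-3)
  # scale invariance and range
  set.seed(5)
  for (i in 1:20) {
    l <- sort(runif(3, 0.1, 3), decreasing = TRUE)
    fa <- compute_fa(l[1], l[2], l[3])
    expect_true(fa >= 0 && fa <= 1)
    expect_equal(fa, compute_fa(10 * l[1], 10 * l[2], 10 * l[3]))
  }
  expect_true(is.na(compute_fa(0, 0, 0)))
})

test_that("tensor fit recovers eigenstructure exactly from noiseless data", {
  dirs <- refmap_directions
  # isotropic
  iso <- fit_tensor(rep(2, 12), dirs)
  expect_equal(iso$MD, 2, tolerance = 1e-12)
  expect_equal(iso$FA, 0, tolerance = 1e-9)
  expect_equal(iso$Dtax, 2, tolerance = 1e-9)
  expect_equal(iso$Dtrad, 2, tolerance = 1e-9)
  # anisotropic about z: medulla-like eigenvalues
  lam <- c(2.44, 1.61, 1.61)
  D <- diag(rev(lam))       # principal axis along z
  d <- apply(dirs, 1, function(g) drop(t(g) %*% D %*% g))
  tf <- fit_tensor(d, dirs)
  expect_equal(tf$eigenvalues, lam, tolerance = 1e-10)
  expect_equal(tf$FA, 0.2487015, tolerance = 5e-4)
  expect_equal(tf$residual, 0, tolerance = 1e-10)
  expect_equal(abs(tf$eigenvectors[3, 1]), 1, tolerance = 1e-9)
  # MD identity to machine precision
  expect_equal(tf$MD, (tf$Dtax + 2 * tf$Dtrad) / 3, tolerance = 1e-15)
  # degenerate stick
  stick <- fit_tensor(dirs[, 1]^2, dirs)   # D = e_x e_x'
  expect_equal(stick$FA, 1, tolerance = 1e-6)
})

test_that("tensor fit flags deficient inputs", {
  dirs <- refmap_directions
  expect_false(fit_tensor(c(2, 2, 2, 2, 2, NA, NA, NA, NA, NA, NA, NA),
                          dirs)$valid)
  # coplanar directions: rank-deficient design
  cop <- cbind(cos(seq(0, pi, length.out = 8)),
               sin(seq(0, pi, length.out = 8)), 0)
  expect_false(fit_tensor(rep(2, 8), cop)$valid)
  # negative eigenvalues clamped and flagged
  d <- apply(dirs, 1, function(g) drop(t(g) %*% diag(c(2, 1, -0.3)) %*% g))
  tf <- fit_tensor(d, dirs)
  expect_true(tf$clamped)
  expect_gte(min(tf$eigenvalues), 0)
})

test_that("tensor estimation is rotation-equivariant", {
  set.seed(8)
  lam <- c(2.5, 1.4, 0.9)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  D <- Q %*% diag(lam) %*% t(Q)
  dirs <- refmap_directions
  d0 <- apply(dirs, 1, function(g) drop(t(g) %*% D %*% g))
  t0 <- fit_tensor(d0, dirs)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  dirs_r <- dirs %*% t(R)
  Dr <- R %*% D %*% t(R)
  dr <- apply(dirs_r, 1, function(g) drop(t(g) %*% Dr %*% g))
  tr <- fit_tensor(dr, dirs_r)
  expect_equal(t0$eigenvalues, tr$eigenvalues, tolerance = 1e-9)
  expect_equal(t0$FA, tr$FA, tolerance = 1e-9)
  expect_equal(t0$MD, tr$MD, tolerance = 1e-9)
})

test_that("pseudodiffusion projection recovers shared-eigenframe amplitudes", {
  dirs <- refmap_directions
  E <- diag(3)
  # isotropic pseudodiffusion: all outputs equal the constant
  iso <- project_pseudodiffusion(rep(30, 12), dirs, E)
  expect_equal(iso$Dp_ax, 30, tolerance = 1e-9)
  expect_equal(iso$Dp_rad, 30, tolerance = 1e-9)
  expect_equal(iso$Dp, 30, tolerance = 1e-9)
  # amplitudes (60, 20, 20): exact recovery from noiseless 12-direction data
  a_true <- c(60, 20, 20)
  dp_j <- drop((dirs %*% E)^2 %*% a_true)
  pr <- project_pseudodiffusion(dp_j, dirs, E)
  expect_equal(pr$amplitudes, a_true, tolerance = 1e-9)
  expect_equal(pr$Dp_ax, 60, tolerance = 1e-9)
  expect_equal(pr$Dp_rad, 20, tolerance = 1e-9)
  expect_equal(pr$Dp, (60 + 20 + 20) / 3, tolerance = 1e-9)
  # identity Dp = (Dp_ax + 2 Dp_rad) / 3 to machine precision
  expect_equal(pr$Dp, (pr$Dp_ax + 2 * pr$Dp_rad) / 3, tolerance = 1e-15)
  # permuting the two minor eigenvectors leaves Dp_rad unchanged
  Eperm <- E[, c(1, 3, 2)]
  pr2 <- project_pseudodiffusion(dp_j, dirs, Eperm)
  expect_equal(pr2$Dp_rad, pr$Dp_rad, tolerance = 1e-9)
  # too few defined directions
  short <- dp_j; short[1:8] <- NA
  expect_false(project_pseudodiffusion(short, dirs, E)$valid)
})

test_that("per-direction fits match the per-direction closed-form truth", {
  ph <- make_phantom(small_phantom_config())
  ser <- synthesize_dwi(ph, study_scheme(), sigma = 0)
  n3 <- prod(dim(ph$labels))
  # pick medulla voxels with identifiable perfusion
  cand <- which(ph$labels == 2L)
  cand <- cand[ph$bipolar_diastole$fp[cand] > 0.1][1:3]
  mask <- array(FALSE, dim(ph$labels)); mask[cand] <- TRUE
  df <- fit_ivim_directional(ser, mask)
  for (v in cand) {
    E <- sapply(1:3, function(i) ph$evec[v + (0:2) * n3 + (i - 1) * 3 * n3])
    lam <- ph$bipolar_diastole$lambda[v + (0:2) * n3]
    for (j in seq_len(nrow(df$directions))) {
      ci <- drop(t(E) %*% df$directions[j, ])^2
      dt_truth <- sum(lam * ci)
      expect_lt(abs(df$Dt[v + (j - 1) * n3] - dt_truth) / dt_truth, 1e-3)
    }
  }
})

test_that("an isotropic noiseless voxel gives equal per-direction diffusivities", {
  # analytic signals, no phantom needed
  sch <- study_scheme()
  b <- sch$bval / 1000
  sig4d <- array(0, c(1, 1, 1, length(b)))
  sig4d[1, 1, 1, ] <- ivim_signal(b, 100, 0.15, 2, 40)
  ser <- dwi_series(sig4d, sch)
  mask <- array(TRUE, c(1, 1, 1))
  df <- fit_ivim_directional(ser, mask)
  dts <- df$Dt[1, 1, 1, ]
  expect_lt(diff(range(dts)), 1e-6)
  # one corrupted direction is flagged without contaminating the rest
  j_bad <- which(sch$bval == 600)[5]
  sig4d[1, 1, 1, j_bad] <- 0
  ser2 <- dwi_series(sig4d, sch)
  df2 <- fit_ivim_directional(ser2, mask)
  expect_identical(df2$status[1, 1, 1, 5], "failed")
  expect_true(all(df2$status[1, 1, 1, -5] == "ok"))
  expect_equal(df2$Dt[1, 1, 1, -5], dts[-5], tolerance = 1e-12)
})

test_that("full directional maps recover phantom ground truth noiselessly", {
  ph <- make_phantom(small_phantom_config())
  ser <- synthesize_dwi(ph, study_scheme(), sigma = 0)
  n3 <- prod(dim(ph$labels))
  cand <- which(ph$labels == 2L)
  cand <- cand[ph$bipolar_diastole$fp[cand] > 0.1][1:4]
  mask <- array(FALSE, dim(ph$labels)); mask[cand] <- TRUE
  maps <- refmap_fit(ser, mask)
  for (v in cand) {
    lam <- ph$bipolar_diastole$lambda[v + (0:2) * n3]
    lamp <- ph$bipolar_diastole$lambda_p[v + (0:2) * n3]
    expect_lt(abs(maps$MD[v] - mean(lam)) / mean(lam), 1e-2)
    expect_lt(abs(maps$FA[v] - compute_fa(lam[1], lam[2], lam[3])) /
                compute_fa(lam[1], lam[2], lam[3]), 1e-2)
    expect_lt(abs(maps$Dtax[v] - lam[1]) / lam[1], 1e-2)
    expect_lt(abs(maps$Dtrad[v] - mean(lam[2:3])) / mean(lam[2:3]), 1e-2)
    expect_lt(abs(maps$f[v] - ph$bipolar_diastole$fp[v]) /
                ph$bipolar_diastole$fp[v], 1e-2)
    expect_lt(abs(maps$Dp_ax[v] - lamp[1]) / lamp[1], 1e-2)
    expect_lt(abs(maps$Dp_rad[v] - mean(lamp[2:3])) / mean(lamp[2:3]), 1e-2)
    # exact internal identities
    expect_equal(maps$MD[v], (maps$Dtax[v] + 2 * maps$Dtrad[v]) / 3,
                 tolerance = 1e-14)
    expect_equal(maps$Dp[v], (maps$Dp_ax[v] + 2 * maps$Dp_rad[v]) / 3,
                 tolerance = 1e-14)
  }
  # determinism
  maps2 <- refmap_fit(ser, mask)
  expect_identical(maps$MD, maps2$MD)
  expect_identical(maps$Dp, maps2$Dp)
})
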