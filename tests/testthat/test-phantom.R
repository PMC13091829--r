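test_that("phantom generation is deterministic under a fixed seed", {
  a <- make_phantom(small_phantom_config(seed = 11))
  b <- make_phantom(small_phantom_config(seed = 11))
  expect_identical(a, b)
  c <- make_phantom(small_phantom_config(seed = 12))
  expect_false(identical(a$bipolar_diastole$fp, c$bipolar_diastole$fp))
})

test_that("phantom geometry partitions the grid with all tissue labels", {
  ph <- make_phantom(small_phantom_config())
  expect_true(all(ph$labels %in% 0:3))
  expect_gt(sum(ph$labels == 1L), 0)   # cortex strip
  expect_gt(sum(ph$labels == 2L), 0)   # medullary pyramids
  expect_gt(sum(ph$labels == 3L), 0)   # excluded pelvis
  # eigenvectors orthonormal on tissue voxels
  n3 <- prod(dim(ph$labels))
  v <- which(ph$labels %in% 1:2)[c(1, 50, 100)]
  for (vi in v) {
    E <- sapply(1:3, function(i) ph$evec[vi + (0:2) * n3 + (i - 1) * 3 * n3])
    expect_equal(crossprod(E), diag(3), tolerance = 1e-12)
  }
  # medulla principal axis is radial (unit vector toward the pelvis/center)
  g <- dim(ph$labels); ctr <- (g + 1) / 2; semi <- 0.45 * g
  vm <- which(ph$labels == 2L)[1]
  xyz <- arrayInd(vm, g)
  w <- (xyz - ctr) / semi; w <- w / sqrt(sum(w^2))
  e1 <- ph$evec[vm + (0:2) * n3]
  expect_equal(abs(sum(w * e1)), 1, tolerance = 1e-9)
})

test_that("generated tensors hit configured FA and MD targets", {
  ph <- make_phantom(phantom_config(grid = c(30, 30, 10), seed = 3))
  n3 <- prod(dim(ph$labels))
  for (tis in c(cortex = 1L, medulla = 2L)) {
    v <- which(ph$labels == tis)
    lam <- sapply(0:2, function(i) ph$bipolar_diastole$lambda[v + i * n3])
    fa <- compute_fa(lam[, 1], lam[, 2], lam[, 3])
    md <- rowMeans(lam)
    target_fa <- if (tis == 1L) 0.19 else 0.28
    target_md <- if (tis == 1L) 1.95 else 1.88
    expect_lt(abs(mean(fa) - target_fa), 0.02)
    expect_lt(abs(mean(md) - target_md), 0.02)
    # invariants: lambda1 >= lambda2 >= lambda3 > 0; pseudodiffusion
    # eigenvalues exceed the largest structural eigenvalue
    expect_true(all(lam[, 1] >= lam[, 2] & lam[, 2] >= lam[, 3] & lam[, 3] > 0))
    lamp <- sapply(0:2, function(i) ph$bipolar_diastole$lambda_p[v + i * n3])
    expect_true(all(lamp > lam[, 1]))
  }
})

test_that("configured eigenvalue triple yields the closed-form MD", {
  # medulla lambda = (2.44, 1.61, 1.61) corresponds to MD = 1.8867, FA = 0.2487
  lam <- c(2.44, 1.61, 1.61)
  tp <- default_tissue_params()
  sel <- tp$tissue == "medulla"
  tp$md_mean[sel] <- mean(lam)
  tp$fa_mean[sel] <- compute_fa(lam[1], lam[2], lam[3])
  ph <- make_phantom(phantom_config(grid = c(30, 30, 10), seed = 5,
                                    tissue_params = tp))
  n3 <- prod(dim(ph$labels))
  v <- which(ph$labels == 2L)
  md <- rowMeans(sapply(0:2, function(i) ph$bipolar_diastole$lambda[v + i * n3]))
  expect_equal(mean(md), 1.886667, tolerance = 0.02)
})

test_that("phantom configuration errors are caught", {
  expect_error(phantom_config(grid = c(4, 4, 2)), ">= 6")
  expect_error(phantom_config(cortex_thickness = 1.2), "cortex_thickness")
  expect_error(phantom_config(pelvis_radius = 0.9), "pelvis")
  tp <- default_tissue_params(); tp$md_mean[1] <- -1
  expect_error(phantom_config(tissue_params = tp), "> 0")
})

test_that("noiseless synthesized signal honours the biexponential model", {
  ph <- make_phantom(small_phantom_config())
  sch <- study_scheme("bipolar", "diastole")
  ser <- synthesize_dwi(ph, sch, sigma = 0)
  n3 <- prod(dim(ph$labels))
  v <- which(ph$labels == 1L)[c(1, 11, 31)]
  sig <- matrix(ser$signal, n3, length(sch$bval))[v, ]
  # b = 0 identity
  expect_equal(sig[, 1], ph$bipolar_diastole$s0[v])
  # per-direction closed form: S = S0 (fp e^{-b g'Dp g} + (1-fp) e^{-b g'Dt g})
  for (vi in v) {
    E <- sapply(1:3, function(i) ph$evec[vi + (0:2) * n3 + (i - 1) * 3 * n3])
    lam <- ph$bipolar_diastole$lambda[vi + (0:2) * n3]
    lamp <- ph$bipolar_diastole$lambda_p[vi + (0:2) * n3]
    j <- which(sch$bval == 800)[4]
    gj <- sch$bvec[, j]
    ci <- drop(t(E) %*% gj)^2
    expected <- ivim_signal(0.8, ph$bipolar_diastole$s0[vi],
                            ph$bipolar_diastole$fp[vi],
                            sum(lam * ci), sum(lamp * ci))
    xyz <- arrayInd(vi, dim(ph$labels))
    expect_equal(ser$signal[xyz[1], xyz[2], xyz[3], j], expected,
                 tolerance = 1e-12)
  }
  # strictly decreasing in b along every direction (noiseless)
  dirs <- t(sch$bvec[, sch$bval > 0])
  j1 <- which(colSums(abs(t(dirs) - dirs[1, ])) < 1e-9)
  ord <- order(sch$bval[sch$bval > 0][j1])
  curve <- cbind(sig[, 1], sig[, which(sch$bval > 0)[j1[ord]], drop = FALSE])
  expect_true(all(apply(curve, 1, function(s) all(diff(s) < 0))))
})

test_that("Rician noise matches the closed-form Rician mean", {
  # 1e4 replicates of one voxel at b=0: sample mean within 1% of the
  # analytic Rician mean (oracle: scaled-Bessel closed form)
  s0 <- 100; sigma <- 2
  set.seed(42)
  n1 <- rnorm(1e4, 0, sigma); n2 <- rnorm(1e4, 0, sigma)
  samp <- sqrt((s0 + n1)^2 + n2^2)
  expect_lt(abs(mean(samp) - rician_mean(s0, sigma)) / rician_mean(s0, sigma),
            0.01)
  # and the synthesizer's noise at b=0 reproduces the same statistic:
  # background-free voxel replicated via repeated seeds is costly, so check
  # the full-volume b=0 distribution against per-voxel Rician means
  ph <- make_phantom(small_phantom_config())
  ser <- synthesize_dwi(ph, study_scheme(), sigma = 20, seed = 9)
  v <- which(ph$labels %in% 1:2)
  expected <- vapply(ph$bipolar_diastole$s0[v], rician_mean,
                     numeric(1), sigma = 20)
  got <- matrix(ser$signal, prod(dim(ph$labels)), 133)[v, 1]
  expect_lt(abs(mean(got) - mean(expected)) / mean(expected), 0.01)
})

test_that("synthesis is deterministic and validates inputs", {
  ph <- make_phantom(small_phantom_config())
  a <- synthesize_dwi(ph, study_scheme(), sigma = 15, seed = 4)
  b <- synthesize_dwi(ph, study_scheme(), sigma = 15, seed = 4)
  expect_identical(a$signal, b$signal)
  expect_error(synthesize_dwi(ph, study_scheme(), sigma = -1), ">= 0")
})
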