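test_that("log-linear fit recovers planted tensors on noiseless phantoms", {
  D <- matrix(c(1.1e-3, 0.1e-3, 0.05e-3,
                0.1e-3, 0.7e-3, -0.08e-3,
                0.05e-3, -0.08e-3, 0.5e-3), 3, 3)
  ph <- generate_dwi_phantom(tiny_phantom(D))
  tf <- fit_tensor(ph$acq)
  expect_lt(max(abs(tf$D - ph$truth$D)), 1e-10)
})

test_that("isotropic phantom yields FA = 0 and MD = d everywhere", {
  d <- 0.8e-3
  ph <- generate_dwi_phantom(tiny_phantom(diag(d, 3)))
  maps <- derive_maps(fit_tensor(ph$acq))
  expect_lt(max(abs(maps$fa)), 1e-10)
  expect_equal(max(abs(maps$md - d)), 0, tolerance = 1e-12)
  expect_equal(max(abs(maps$dxx - d)), 0, tolerance = 1e-12)
})

test_that("FA of a prolate tensor matches the closed-form eigenvalue oracle", {
  l <- c(1.7e-3, 0.3e-3, 0.3e-3)
  ph <- generate_dwi_phantom(tiny_phantom(diag(l)))
  tf <- fit_tensor(ph$acq)
  maps <- derive_maps(tf)
  expect_lt(max(abs(tf$D - ph$truth$D)), 1e-10)
  # frozen from fa_oracle(c(1.7, 0.3, 0.3) * 1e-3)
  expect_equal(fa_oracle(l), 0.79902, tolerance = 1e-5)
  expect_equal(unique(round(as.vector(maps$fa), 10)), round(fa_oracle(l), 10))
})

test_that("diagonal tensors read off as Dxx/Dyy/Dzz; rotation follows R D R'", {
  a <- 1.4e-3; b <- 0.6e-3; cc <- 0.4e-3
  ph <- generate_dwi_phantom(tiny_phantom(diag(c(a, b, cc))))
  maps <- derive_maps(fit_tensor(ph$acq))
  expect_equal(maps$dxx[1, 1, 1], a, tolerance = 1e-12)
  expect_equal(maps$dyy[1, 1, 1], b, tolerance = 1e-12)
  expect_equal(maps$dzz[1, 1, 1], cc, tolerance = 1e-12)
  # 90 degree rotation about z: explicit R D R' arithmetic as the oracle
  R <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  Drot <- R %*% diag(c(a, b, cc)) %*% t(R)
  ph2 <- generate_dwi_phantom(tiny_phantom(Drot))
  maps2 <- derive_maps(fit_tensor(ph2$acq))
  expect_equal(maps2$dxx[1, 1, 1], b, tolerance = 1e-12)
  expect_equal(maps2$dyy[1, 1, 1], a, tolerance = 1e-12)
  expect_equal(maps2$dzz[1, 1, 1], cc, tolerance = 1e-12)
})

test_that("fit is invariant to reordering of the DWI volumes", {
  D <- diag(c(1.2e-3, 0.6e-3, 0.4e-3))
  ph <- generate_dwi_phantom(tiny_phantom(D))
  acq <- ph$acq
  set.seed(11)
  perm <- sample(length(acq$bvals))
  acq2 <- dwi_acquisition(acq$signal[, , , perm], acq$bvals[perm],
                          acq$bvecs[, perm], acq$affine)
  m1 <- derive_maps(fit_tensor(acq))
  m2 <- derive_maps(fit_tensor(acq2))
  expect_equal(m1$dxx, m2$dxx, tolerance = 1e-12)
  expect_equal(m1$fa, m2$fa, tolerance = 1e-12)
})

test_that("rotating gradients and tensor together leaves FA and MD unchanged", {
  D <- diag(c(1.5e-3, 0.6e-3, 0.3e-3))
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  dirs <- default_gradient_set(15)
  s1 <- phantom_spec(shape = c(3, 3, 3), background_tensor = D,
                     directions = dirs)
  s2 <- phantom_spec(shape = c(3, 3, 3), background_tensor = R %*% D %*% t(R),
                     directions = dirs %*% t(R))
  m1 <- derive_maps(fit_tensor(generate_dwi_phantom(s1)$acq))
  m2 <- derive_maps(fit_tensor(generate_dwi_phantom(s2)$acq))
  expect_lt(max(abs(m1$fa - m2$fa)), 1e-9)
  expect_lt(max(abs(m1$md - m2$md)), 1e-9)
})

test_that("zero signal is floored (fit proceeds) and all-zero voxels are invalid", {
  ph <- generate_dwi_phantom(tiny_phantom(diag(0.8e-3, 3), shape = c(3, 3, 3)))
  sig <- ph$acq$signal
  sig[1, 1, 1, 10] <- 0          # one dead measurement
  sig[3, 3, 3, ] <- 0            # a dead voxel
  acq <- dwi_acquisition(sig, ph$acq$bvals, ph$acq$bvecs, ph$acq$affine)
  tf <- fit_tensor(acq)
  expect_false(tf$valid[3, 3, 3])
  expect_true(tf$valid[1, 1, 1])
  expect_gte(tf$qc$n_floored, 1)
  expect_identical(tf$qc$n_invalid, 1L)
  expect_true(all(is.finite(tf$D[1, 1, 1, ])))
})

test_that("fewer than 6 independent directions is a rank error", {
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  sig <- array(1000, dim = c(2, 2, 2, 5))
  bv <- c(0, 0, rep(1000, 3))
  g <- cbind(matrix(0, 3, 2), t(dirs))
  expect_error(dwi_acquisition(sig, bv, g, diag(4)), "non-collinear")
})

test_that("median WM MD matches direct medians and a sort oracle", {
  d <- 0.9e-3
  ph <- generate_dwi_phantom(tiny_phantom(diag(d, 3)))
  maps <- derive_maps(fit_tensor(ph$acq))
  wm <- array(TRUE, dim = dim(maps$md))
  expect_equal(median_md(maps, wm), d, tolerance = 1e-12)
  # synthetic MD field: sort-based oracle on 10000 values
  set.seed(21)
  vals <- rlnorm(10000, log(0.9e-3), 0.2)
  dims <- c(25L, 20L, 20L)
  maps2 <- structure(list(md = array(vals, dims),
                          valid = array(TRUE, dims)),
                     class = "diffusivity_maps")
  srt <- sort(vals)
  n <- length(srt)
  orc <- if (n %% 2 == 1) srt[(n + 1) / 2] else mean(srt[n / 2 + 0:1])
  expect_identical(median_md(maps2, array(TRUE, dims)), orc)
  # odd-count hand case
  maps3 <- maps
  maps3$md[] <- 2e-3
  maps3$md[1, 1, 1] <- 1e-3; maps3$md[2, 1, 1] <- 3e-3
  wm3 <- array(FALSE, dim = dim(maps$md)); wm3[1:3, 1, 1] <- TRUE
  expect_identical(median_md(maps3, wm3), 2e-3)
  expect_error(median_md(maps, array(FALSE, dim = dim(maps$md))), "mask")
})

test_that("PSMD is the p95 - p5 spread of skeleton MD", {
  ph <- generate_dwi_phantom(tiny_phantom(diag(0.8e-3, 3)))
  maps <- derive_maps(fit_tensor(ph$acq))
  skel <- array(TRUE, dim = dim(maps$md))
  expect_equal(psmd(maps, skel), 0, tolerance = 1e-15)
  # uniform MD on [0.6, 1.2]e-3: analytic p95 - p5 = 0.9 * range
  set.seed(31)
  dims <- c(25L, 20L, 20L); n <- prod(dims)
  mapsU <- structure(list(md = array(runif(n, 0.6e-3, 1.2e-3), dims),
                          valid = array(TRUE, dims)),
                     class = "diffusivity_maps")
  se <- 0.6e-3 * sqrt(0.05 * 0.95 / n) * 2  # rough SE of each percentile
  expect_equal(psmd(mapsU, array(TRUE, dims)), 0.9 * 0.6e-3,
               tolerance = 3 * se / (0.9 * 0.6e-3))
  # two-voxel skeleton against the stated interpolation convention
  maps$md[1, 1, 1] <- 1e-3; maps$md[2, 1, 1] <- 2e-3
  skel2 <- array(FALSE, dim = dim(maps$md)); skel2[1:2, 1, 1] <- TRUE
  q <- quantile(c(1e-3, 2e-3), c(0.05, 0.95), type = 7)
  expect_equal(psmd(maps, skel2), unname(q[2] - q[1]))
  expect_error(psmd(maps, array(FALSE, dim = dim(maps$md))), "mask")
})

test_that("FA stays in [0,1] for SPD tensors and is 0 only at isotropy", {
  set.seed(41)
  for (i in 1:25) {
    A <- matrix(rnorm(9), 3, 3)
    D <- crossprod(A) * 1e-4 + diag(1e-5, 3)
    ph <- generate_dwi_phantom(tiny_phantom(D, shape = c(2, 2, 2), n_dirs = 12))
    maps <- derive_maps(fit_tensor(ph$acq))
    fa <- maps$fa[1, 1, 1]
    expect_gte(fa, 0); expect_lte(fa, 1 + 1e-12)
    l <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    if (max(l) - min(l) > 1e-12) expect_gt(fa, 0)
  }
})
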