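test_that("default ROI set has the canonical centers, sides and roles", {
  rois <- build_roi_set()
  get <- function(s, r) rois[rois$side == s & rois$role == r, c("x", "y", "z")]
  expect_equal(unlist(get("right", "projection"), use.names = FALSE), c(24, -12, 24))
  expect_equal(unlist(get("right", "association"), use.names = FALSE), c(36, -12, 24))
  expect_equal(unlist(get("left", "projection"), use.names = FALSE), c(-28, -12, 24))
  expect_equal(unlist(get("left", "association"), use.names = FALSE), c(-40, -12, 24))
  expect_true(all(rois$diameter == 6))
})

test_that("degenerate ROI geometry is rejected, wider spheres stay disjoint", {
  bad <- DEFAULT_ALPS_CENTERS
  bad[3, 1] <- -24       # two ROIs with |x| = 24 on the left: roles ambiguous
  expect_error(build_roi_set(bad), "side")
  expect_silent(build_roi_set(diameter = 8))   # centers >= 12 mm apart per side
  expect_error(build_roi_set(diameter = 13), "overlap")
})

test_that("sphere rasterization equals brute-force enumeration at 1 mm and 2.5 mm", {
  rois <- build_roi_set()
  roi <- rois[1, ]
  # 1 mm grid with a voxel center exactly on the ROI center
  shape1 <- c(21L, 21L, 21L)
  aff1 <- scaled_affine_for_test(1, roi)
  m1 <- rasterize_roi(roi, shape1, aff1)
  expect_identical(sum(m1), sphere_count_oracle(c(roi$x, roi$y, roi$z), 3,
                                                shape1, aff1))
  expect_identical(sum(m1), 123L)  # integer lattice points with x^2+y^2+z^2 <= 9
  # the voxel at the ROI center is always included
  ctr_idx <- round(solve(aff1) %*% c(roi$x, roi$y, roi$z, 1))[1:3] + 1
  expect_true(m1[ctr_idx[1], ctr_idx[2], ctr_idx[3]])
  # acquisition-resolution grid
  shape2 <- c(9L, 9L, 9L)
  aff2 <- scaled_affine_for_test(2.5, roi)
  m2 <- rasterize_roi(roi, shape2, aff2)
  expect_identical(sum(m2), sphere_count_oracle(c(roi$x, roi$y, roi$z), 3,
                                                shape2, aff2))
  expect_error(rasterize_roi(roi, c(3L, 3L, 3L), scaled_affine(1, c(500, 0, 0))),
               "no voxel")
})

test_that("planted-diffusivity phantoms give the closed-form index end to end", {
  cases <- list(
    list(v = c(1.0, 1.0, 1.0, 1.0) * 1e-3, mean = 1.0),
    list(v = c(1.5, 1.5, 0.5, 0.5) * 1e-3, mean = 3.0),
    list(v = c(1.2, 0.8, 0.5, 0.5) * 1e-3, mean = 2.0)
  )
  for (cs in cases) {
    ph <- generate_alps_phantom(cs$v[1], cs$v[2], cs$v[3], cs$v[4])
    res <- compute_alps(derive_maps(fit_tensor(ph$acq)), ph$rois)
    expect_equal(res$mean, cs$mean, tolerance = 1e-9)
    expect_equal(res$left, res$right, tolerance = 1e-9)
  }
})

test_that("asymmetric phantom: left 2.0, right 1.0, mean 1.5 through the full path", {
  ph <- generate_alps_phantom(1.0e-3, 1.0e-3, 1.0e-3, 1.0e-3,
                              left = list(dxx_proj = 2.0e-3, dxx_assoc = 2.0e-3))
  expect_equal(ph$expected$left, 2.0)
  expect_equal(ph$expected$right, 1.0)
  res <- compute_alps(derive_maps(fit_tensor(ph$acq)), ph$rois)
  expect_equal(res$left, 2.0, tolerance = 1e-9)
  expect_equal(res$right, 1.0, tolerance = 1e-9)
  expect_equal(res$mean, 1.5, tolerance = 1e-9)
  # native-grid sampling agrees on phantoms
  res_n <- compute_alps(derive_maps(fit_tensor(ph$acq)), ph$rois,
                        method = "native")
  expect_equal(res_n$mean, 1.5, tolerance = 1e-9)
})

test_that("mirroring the maps about the midsagittal plane swaps left and right", {
  # the canonical ROI centers are not mirror images (|x| = 24/36 right,
  # 28/40 left), so the exact swap property is checked on a symmetric
  # override of the ROI layout
  sym <- build_roi_set(matrix(c(24, -12, 24, -24, -12, 24,
                                36, -12, 24, -36, -12, 24),
                              ncol = 3, byrow = TRUE))
  ph <- generate_alps_phantom(1.0e-3, 1.0e-3, 1.0e-3, 1.0e-3,
                              left = list(dxx_proj = 1.8e-3), rois = sym)
  maps <- derive_maps(fit_tensor(ph$acq))
  res <- compute_alps(maps, ph$rois)
  # mirrored volume: reverse the x axis and compose the affine so the
  # world x coordinate is negated
  n <- dim(maps$dxx)[1]
  flip <- function(a) a[n:1, , , drop = FALSE]
  P <- diag(4); P[1, 1] <- -1; P[1, 4] <- n - 1   # voxel i -> n-1-i
  Fx <- diag(c(-1, 1, 1, 1))
  mirrored <- maps
  for (nm in c("dxx", "dyy", "dzz", "fa", "md")) mirrored[[nm]] <- flip(maps[[nm]])
  mirrored$valid <- flip(maps$valid)
  mirrored$affine <- Fx %*% maps$affine %*% P
  res_m <- compute_alps(mirrored, sym)
  expect_equal(res_m$left, res$right, tolerance = 1e-9)
  expect_equal(res_m$right, res$left, tolerance = 1e-9)
  expect_equal(res_m$mean, res$mean, tolerance = 1e-9)
})

test_that("the index is scale invariant and monotone in the planted diffusivities", {
  ph <- generate_alps_phantom(1.2e-3, 0.9e-3, 0.6e-3, 0.5e-3)
  maps <- derive_maps(fit_tensor(ph$acq))
  res <- compute_alps(maps, ph$rois)
  scaled <- maps
  for (nm in c("dxx", "dyy", "dzz")) scaled[[nm]] <- maps[[nm]] * 3.7
  res_s <- compute_alps(scaled, ph$rois)
  expect_equal(res_s$left, res$left, tolerance = 1e-12)
  expect_equal(res_s$mean, res$mean, tolerance = 1e-12)
  # monotonicity through the full pipeline
  up <- compute_alps(derive_maps(fit_tensor(
    generate_alps_phantom(1.3e-3, 0.9e-3, 0.6e-3, 0.5e-3)$acq)), ph$rois)
  expect_gt(up$mean, res$mean)
  dn <- compute_alps(derive_maps(fit_tensor(
    generate_alps_phantom(1.2e-3, 0.9e-3, 0.7e-3, 0.5e-3)$acq)), ph$rois)
  expect_lt(dn$mean, res$mean)
})

test_that("invalid voxels are excluded from ROI means and counted in QC", {
  ph <- generate_alps_phantom(1.2e-3, 0.8e-3, 0.5e-3, 0.5e-3)
  sig <- ph$acq$signal
  rois <- ph$rois
  # kill one voxel inside the right-projection ROI
  vox <- round(solve(ph$acq$affine) %*% c(24, -12, 24, 1))[1:3] + 1
  sig[vox[1], vox[2], vox[3], ] <- 0
  acq <- dwi_acquisition(sig, ph$acq$bvals, ph$acq$bvecs, ph$acq$affine)
  maps <- derive_maps(fit_tensor(acq))
  res <- compute_alps(maps, rois)
  expect_gt(res$qc$n_invalid_total, 0)
  expect_equal(res$mean, 2.0, tolerance = 1e-9)   # means unbiased by the bad voxel
  res_n <- compute_alps(maps, rois, method = "native")
  expect_equal(res_n$mean, 2.0, tolerance = 1e-9)
})

test_that("non-physical diffusivities in the denominator raise an error", {
  ph <- generate_alps_phantom(1.0e-3, 1.0e-3, 1.0e-3, 1.0e-3)
  maps <- derive_maps(fit_tensor(ph$acq))
  maps$dyy[] <- -1e-3
  maps$dzz[] <- -1e-3
  expect_error(compute_alps(maps, ph$rois), "non-physical")
})

test_that("orientation QC flags ROIs whose fibers point the wrong way", {
  ph <- generate_alps_phantom(1.0e-3, 1.0e-3, 0.5e-3, 0.5e-3)
  tf <- fit_tensor(ph$acq)
  qc <- roi_orientation_qc(tf, ph$rois)
  expect_true(all(qc$aligned_fraction == 1))
  expect_false(any(qc$warn))
  # plant x-dominant tensors into an association ROI: fraction 0, warning
  shape <- dim(tf$D)[1:3]
  roi_a <- ph$rois[ph$rois$side == "right" & ph$rois$role == "association", ]
  sel <- rasterize_roi(roi_a, shape, tf$affine)
  D <- tf$D
  for (cmp in 1:6) {
    v <- D[, , , cmp]
    v[sel] <- c(1.5e-3, 0.5e-3, 0.5e-3, 0, 0, 0)[cmp]
    D[, , , cmp] <- v
  }
  tf2 <- tensor_field(D, tf$affine, tf$valid)
  qc2 <- roi_orientation_qc(tf2, ph$rois)
  row <- qc2[qc2$side == "right" & qc2$role == "association", ]
  expect_equal(row$aligned_fraction, 0)
  expect_true(row$warn)
  # mixed 60/40 z/y in a projection ROI: fraction by direct count, passes at 0.5
  roi_p <- ph$rois[ph$rois$side == "right" & ph$rois$role == "projection", ]
  selp <- which(rasterize_roi(roi_p, shape, tf$affine))
  ny <- floor(0.4 * length(selp))
  yvox <- selp[seq_len(ny)]
  D3 <- tf$D
  for (cmp in 1:6) {
    v <- D3[, , , cmp]
    v[yvox] <- c(0.5e-3, 1.5e-3, 0.5e-3, 0, 0, 0)[cmp]  # y-dominant
    D3[, , , cmp] <- v
  }
  tf3 <- tensor_field(D3, tf$affine, tf$valid)
  qc3 <- roi_orientation_qc(tf3, ph$rois)
  rowp <- qc3[qc3$side == "right" & qc3$role == "projection", ]
  expect_equal(rowp$aligned_fraction, 1 - ny / length(selp))
  expect_false(rowp$warn)
})
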