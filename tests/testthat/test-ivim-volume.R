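noiseless_phantom <- function(f = 0) {
  dim <- c(8L, 8L, 2L)
  tumor <- array(FALSE, dim); tumor[3:6, 3:6, ] <- TRUE
  spec <- phantom_spec(dim = dim,
                       compartments = list(tumor = list(
                         mask = tumor, gt = ivim_ground_truth(1.4e-3, 0.01, f))),
                       snr_b0 = Inf, seed = 1)
  generate_dwi_phantom(spec)
}

test_that("noiseless single-compartment maps reproduce ground truth", {
  ph <- noiseless_phantom(f = 0)
  maps <- suppressMessages(fit_volume(ph$dwi, ph$b, ph$masks$tumor))
  w <- which(ph$masks$tumor)
  expect_equal(maps$n_failed, 0L)
  expect_true(all(abs(maps$D[w] - 1.4e-3) / 1.4e-3 < 1e-6))
  expect_true(all(abs(maps$ADC[w] - 1.4e-3) / 1.4e-3 < 1e-6))
  expect_true(all(maps$f[w] < 1e-6))
  expect_true(all(is.na(maps$D[-w])))
})

test_that("fit_volume rejects inconsistent inputs and empty masks", {
  ph <- noiseless_phantom()
  expect_error(fit_volume(ph$dwi, ph$b[-1], ph$masks$tumor), "does not match")
  empty <- array(FALSE, dim(ph$masks$tumor))
  expect_warning(res <- fit_volume(ph$dwi, ph$b, empty), "empty mask")
  expect_equal(res$n_failed, 0L)
  expect_true(all(is.na(res$D)))
})

test_that("map values do not depend on voxel visiting order", {
  # fitting is voxel-separable; permuting the grid then unpermuting the maps
  # must reproduce them
  ph <- noiseless_phantom(f = 0.08)
  maps <- suppressMessages(fit_volume(ph$dwi, ph$b, ph$masks$tumor))
  perm <- c(2, 1, 3)
  dwi_p <- aperm(ph$dwi, c(perm, 4))
  mask_p <- aperm(ph$masks$tumor, perm)
  maps_p <- suppressMessages(fit_volume(dwi_p, ph$b, mask_p))
  expect_equal(aperm(maps_p$D, order(perm)), maps$D)
  expect_equal(aperm(maps_p$f, order(perm)), maps$f)
})

test_that("ROI summaries use converged voxels and the n-1 SD convention", {
  maps <- list(D = array(c(1, 3, NA, 5), c(4, 1, 1)),
               converged = array(c(TRUE, TRUE, FALSE, FALSE), c(4, 1, 1)))
  mask <- array(TRUE, c(4, 1, 1))
  s <- summarize_roi(maps, mask)
  expect_equal(s$mean, 2)
  expect_equal(s$sd, sqrt(2))
  expect_equal(s$n_voxels, 2L)
  expect_equal(s$n_excluded, 2L)

  uni <- list(D = array(7, c(3, 1, 1)), converged = array(TRUE, c(3, 1, 1)))
  s2 <- summarize_roi(uni, array(TRUE, c(3, 1, 1)))
  expect_equal(s2$mean, 7)
  expect_equal(s2$sd, 0)
  expect_error(summarize_roi(uni, array(FALSE, c(3, 1, 1))), "empty")
})

test_that("ROI recovery from a noisy phantom stays within 5% of truth", {
  dim <- c(16L, 16L, 6L)
  tumor <- ellipsoid_mask(dim, center = c(8.5, 8.5, 3.5), radii = c(7, 7, 2.8))
  spec <- phantom_spec(dim = dim,
                       compartments = list(tumor = list(
                         mask = tumor, gt = ivim_ground_truth(1.4e-3, 0.01, 0.08))),
                       snr_b0 = 40, seed = 21)
  ph <- generate_dwi_phantom(spec)
  expect_gte(sum(tumor), 500)
  maps <- suppressMessages(fit_volume(ph$dwi, ph$b, tumor))
  w <- which(tumor)
  med_rel_err <- median(abs(maps$D[w] - 1.4e-3) / 1.4e-3, na.rm = TRUE)
  expect_lt(med_rel_err, 0.10)
  roi <- summarize_roi(maps, tumor)
  expect_lt(abs(roi$mean[roi$parameter == "D"] - 1.4e-3) / 1.4e-3, 0.05)
})

test_that("tumor volume is slice area times thickness", {
  mask <- array(0L, c(10, 10, 3))
  mask[1:5, 1:2, ] <- 1L  # 10 voxels per slice
  v <- compute_tumor_volume(mask, voxel_size = c(0.1, 0.1), slice_thickness = 0.3)
  expect_equal(v$slice_areas, rep(0.1, 3))
  expect_equal(v$volume, 0.09)
  expect_equal(v$volume, sum(v$slice_areas) * v$slice_thickness)

  expect_equal(compute_tumor_volume(array(0L, c(4, 4, 2)), c(0.1, 0.1), 0.3)$volume, 0)
  expect_error(compute_tumor_volume(array(2L, c(2, 2, 1)), c(0.1, 0.1), 0.3), "binary")
})

test_that("rasterized sphere volume approaches the analytic value", {
  r_mm <- 1.5; vox <- 0.05
  n <- ceiling(2 * r_mm / vox) + 4
  dim <- rep(as.integer(n), 3)
  ctr <- (n + 1) / 2
  mask <- ellipsoid_mask(dim, center = rep(ctr, 3), radii = rep(r_mm / vox, 3))
  v <- compute_tumor_volume(mask + 0L, voxel_size = c(vox, vox), slice_thickness = vox)
  expect_equal(v$volume, 4 / 3 * pi * r_mm^3, tolerance = 0.05)
})
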