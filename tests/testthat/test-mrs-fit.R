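test_that("an exact basis member is recovered exactly", {
  fid <- simulate_fid(spectrum_spec(amplitudes = c(tCr = 3)))
  est <- fit_basis(fid, noise_sigma = 1e-3)
  a_tcr <- est$amplitude[est$metabolite == "tCr"]
  expect_equal(a_tcr, 3, tolerance = 1e-6)
  expect_true(all(est$amplitude[est$metabolite != "tCr"] < 1e-6))
})

test_that("CRLB scales linearly with the noise level", {
  amps <- profile_amplitudes()
  fid1 <- simulate_fid(spectrum_spec(amplitudes = amps, noise_sigma = 0.04, seed = 5))
  fid2 <- simulate_fid(spectrum_spec(amplitudes = amps, noise_sigma = 0.02, seed = 5))
  e1 <- fit_basis(fid1, noise_sigma = 0.04)
  e2 <- fit_basis(fid2, noise_sigma = 0.02)
  r <- e1$crlb[e1$metabolite == "tCr"] / e2$crlb[e2$metabolite == "tCr"]
  expect_equal(r, 2, tolerance = 0.1)
})

test_that("amplitudes and CRLBs are scale-equivariant, the fraction invariant", {
  amps <- profile_amplitudes()
  fid <- simulate_fid(spectrum_spec(amplitudes = amps, noise_sigma = 0.02, seed = 9))
  c_ <- 12.5
  fid_s <- new_fid(fid$samples * c_, fid$dwell, fid$transmitter_mhz, fid$ppm_ref)
  e1 <- fit_basis(fid, noise_sigma = 0.02)
  e2 <- fit_basis(fid_s, noise_sigma = 0.02 * c_)
  expect_equal(e2$amplitude, e1$amplitude * c_, tolerance = 1e-4)
  expect_equal(e2$crlb, e1$crlb * c_, tolerance = 1e-4)
  expect_equal(e2$crlb_fraction, e1$crlb_fraction, tolerance = 1e-4)
})

test_that("two-metabolite recovery at SNR 50 is accurate in the median", {
  errs <- matrix(NA_real_, 60, 2)
  for (i in seq_len(nrow(errs))) {
    fid <- simulate_fid(spectrum_spec(amplitudes = c(tCho = 1, tCr = 1),
                                      noise_sigma = 1 / 50, seed = 1000 + i))
    est <- fit_basis(fid, noise_sigma = 1 / 50)
    errs[i, ] <- abs(est$amplitude[match(c("tCho", "tCr"), est$metabolite)] - 1)
  }
  expect_lt(median(errs[, 1]), 0.10)
  expect_lt(median(errs[, 2]), 0.10)
})

test_that("water reference fit recovers amplitude and flags empty input", {
  wf <- simulate_fid(spectrum_spec(amplitudes = c(NAA = 0), water_amplitude = 1000,
                                   water_linewidth = 20))
  r <- fit_water_reference(wf)
  expect_true(r$converged)
  expect_equal(r$amplitude, 1000, tolerance = 1e-6)

  set.seed(77)
  errs <- vapply(1:25, function(i) {
    wfn <- simulate_fid(spectrum_spec(amplitudes = c(NAA = 0), water_amplitude = 1000,
                                      water_linewidth = 20, noise_sigma = 10,
                                      seed = 500 + i))
    abs(fit_water_reference(wfn)$amplitude - 1000) / 1000
  }, numeric(1))
  expect_lt(median(errs), 0.03)

  z <- fit_water_reference(new_fid(complex(real = rep(0, 128)), 1 / 4401, 400))
  expect_false(z$converged)
})

test_that("water-scaling correction factor matches its closed form", {
  wp <- water_scaling_params(water_amplitude = 1)
  # independent high-precision evaluation of the correction factor
  expected <- (1 - exp(-2000 / 2097)) * exp(-16.5 / 42)
  expect_equal(water_correction_factor(wp), expected, tolerance = 1e-12)

  # TR -> Inf, TE -> 0 limit
  wp_lim <- water_scaling_params(1, TR = 1e12, TE = 1e-12)
  expect_equal(water_correction_factor(wp_lim), 1, tolerance = 1e-10)

  expect_equal(water_scale(0, water_scaling_params(1000)), 0)
})

test_that("water scaling is homogeneous in amplitude and water amplitude", {
  wp1 <- water_scaling_params(water_amplitude = 800)
  wp2 <- water_scaling_params(water_amplitude = 1600)
  expect_equal(water_scale(10, wp1), 10 * water_scale(1, wp1))
  expect_equal(water_scale(1, wp2), water_scale(1, wp1) / 2)
})

test_that("CRLB filter implements the 20% rule with zero-amplitude guard", {
  est <- data.frame(metabolite = c("a", "b", "c"),
                    amplitude = c(10, 10, 0), crlb = c(1, 3, 0.1),
                    crlb_fraction = c(0.1, 0.3, Inf), accepted = NA)
  out <- crlb_filter(est)
  expect_identical(out$accepted, c(TRUE, FALSE, FALSE))
  expect_error(crlb_filter(transform(est, crlb = c(-1, 3, 1))), "CRLB")
})

test_that("ratio table respects acceptance and denominator validity", {
  est <- data.frame(
    metabolite = c("tCho", "NAA", "Glx", "LipLac", "tCr", "mI+Gly"),
    amplitude = c(2, 1, 1.5, 2.5, 1, 0.8),
    crlb = 0.01, crlb_fraction = 0.01,
    accepted = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE))
  r <- compute_ratios(est)
  expect_equal(r$value[r$ratio == "tCho/tCr"], 2)
  expect_false(r$valid[r$ratio == "tCho/NAA"])
  expect_true(is.na(r$value[r$ratio == "tCho/NAA"]))
  expect_equal(r$value[r$ratio == "Lip+Lac/tCr"], 2.5)
  expect_equal(r$value[r$ratio == "mI/tCr"], 0.8)
})

test_that("the noiseless chain reproduces a programmed ratio exactly", {
  amps <- c(tCho = 1.59, NAA = 1.28, Glx = 2.0, LipLac = 1.82, tCr = 1.0,
            `mI+Gly` = 0.90)
  fid <- simulate_fid(spectrum_spec(amplitudes = amps, water_amplitude = 100))
  filt <- suppressWarnings(hlsvd_filter(fid))
  proc <- apodize_zerofill(filt)
  est <- crlb_filter(fit_basis(proc, noise_sigma = 1e-4))
  r <- compute_ratios(est)
  expect_equal(r$value[r$ratio == "tCho/tCr"], 1.59, tolerance = 1e-3)
})
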