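test_that("ADC fit is exact on exact monoexponential decay", {
  b <- c(0, default_bvalues())
  s <- dwi_series(b, exp(-b * 1e-3))
  r <- fit_monoexp_adc(s)
  expect_true(r$converged)
  expect_equal(r$ADC, 1e-3, tolerance = 1e-9)

  const <- dwi_series(b, rep(2, length(b)))
  expect_equal(fit_monoexp_adc(const)$ADC, 0, tolerance = 1e-12)

  zero <- dwi_series(b, rep(0, length(b)), S0 = 1)
  expect_false(fit_monoexp_adc(zero)$converged)
})

test_that("ADC on a perfused signal matches the generic curve-fit oracle", {
  s <- protocol_series(D = 1.0e-3, Dstar = 0.01, f = 0.1)
  r <- fit_monoexp_adc(s)
  oracle <- adc_oracle(s$b, s$S / s$S0)
  expect_equal(r$ADC, oracle, tolerance = 1e-6)
})

test_that("high-b linear stage is exact for f = 0 and matches the OLS oracle", {
  b <- c(0, default_bvalues())
  s <- dwi_series(b, 2 * exp(-b * 1.3e-3))
  r <- fit_high_b_linear(s)
  expect_equal(r$D, 1.3e-3, tolerance = 1e-10)
  expect_equal(r$Sint, 2, tolerance = 1e-9)
  expect_equal(r$f_init, 0, tolerance = 1e-9)

  s2 <- protocol_series(D = 1.1e-3, Dstar = 0.01, f = 0.15)
  r2 <- fit_high_b_linear(s2)
  hb <- s2$b > 200
  oracle <- ols_loglinear(s2$b[hb], s2$S[hb])
  expect_equal(r2$D, -oracle$slope, tolerance = 1e-12)
  expect_equal(r2$Sint, exp(oracle$intercept), tolerance = 1e-12)
  # perfusion residue above b = 200 bounds the bias
  expect_lt(abs(r2$D - 1.1e-3) / 1.1e-3, 0.02)
  expect_lt(abs(r2$f_init - 0.15), 0.02)
})

test_that("too few high-b points yield a non-converged flag", {
  s <- dwi_series(c(0, 50, 100, 500), exp(-c(0, 50, 100, 500) * 1e-3))
  r <- fit_high_b_linear(s)
  expect_false(r$converged)
  expect_true(is.na(r$D))
})

test_that("segmented fit recovers parameters where separation holds", {
  # region with well-separated compartments: D* >= 1e-2 at modest f, and the
  # fast-perfusion slice up to f = 0.3
  grid <- rbind(expand.grid(D = c(0.8e-3, 1.2e-3, 1.6e-3), f = c(0.05, 0.1),
                            Ds = c(1e-2, 5e-2)),
                expand.grid(D = c(0.8e-3, 1.2e-3, 1.6e-3), f = c(0.2, 0.3),
                            Ds = 5e-2))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    s <- protocol_series(g$D, g$Ds, g$f)
    p <- fit_segmented_ivim(s)
    expect_true(p$converged)
    expect_lt(abs(p$D - g$D) / g$D, 0.02)
    expect_lt(abs(p$f - g$f), 0.02)
    expect_lt(abs(p$Dstar - g$Ds) / g$Ds, 0.20)
  }
})

test_that("segmented fit agrees with an unconstrained biexponential oracle", {
  s <- protocol_series(D = 1.4e-3, Dstar = 0.01, f = 0.08)
  p <- fit_segmented_ivim(s)
  o <- biexp_oracle(s$b, s$S / s$S0)
  expect_lt(abs(p$D - o$D) / o$D, 0.02)
  expect_lt(abs(p$f - o$f), 0.02)
  expect_lt(abs(p$Dstar - o$Ds) / o$Ds, 0.2)
})

test_that("f = 0 degenerate case returns the one-compartment solution", {
  s <- protocol_series(D = 1.4e-3, Dstar = 0.01, f = 0)
  p <- fit_segmented_ivim(s)
  expect_true(p$converged)
  expect_lte(p$f, 0.01)
  expect_lt(abs(p$D - 1.4e-3) / 1.4e-3, 0.01)
  expect_lt(abs(p$ADC - p$D) / p$D, 0.01)
})

test_that("default pseudo-diffusion start value is 0.01 mm^2/s", {
  expect_equal(ivim_fit_config()$dstar_init, 0.01)
  expect_equal(ivim_fit_config()$high_b_threshold, 200)
})

test_that("estimates are scale-equivariant in the signal", {
  s <- protocol_series(D = 1.2e-3, Dstar = 0.015, f = 0.12)
  p1 <- fit_segmented_ivim(s)
  s2 <- dwi_series(s$b, s$S * 37.5, S0 = s$S0 * 37.5)
  p2 <- fit_segmented_ivim(s2)
  expect_equal(p2$D, p1$D, tolerance = 1e-9)
  expect_equal(p2$f, p1$f, tolerance = 1e-8)
  expect_equal(p2$Dstar, p1$Dstar, tolerance = 1e-6)
  expect_equal(p2$ADC, p1$ADC, tolerance = 1e-9)
  expect_equal(p2$Sint, p1$Sint * 37.5, tolerance = 1e-6)
})

test_that("ADC dominates D on perfused noiseless signals", {
  for (f in c(0.05, 0.1, 0.2)) {
    s <- protocol_series(D = 1e-3, Dstar = 0.02, f = f)
    p <- fit_segmented_ivim(s)
    expect_gte(p$ADC, p$D)
  }
})

test_that("Monte-Carlo recovery at SNR 40 is unbiased in the median", {
  b <- c(rep(0, 5), default_bvalues())
  clean <- simulate_ivim_signal(ivim_ground_truth(1.4e-3, 0.01, 0.08), b)$S
  sigma <- 1 / 40
  set.seed(401)
  n <- 300
  Dh <- fh <- numeric(n)
  for (i in seq_len(n)) {
    S <- sqrt((clean + rnorm(length(b), sd = sigma))^2 + rnorm(length(b), sd = sigma)^2)
    p <- fit_segmented_ivim(dwi_series(b, S))
    Dh[i] <- p$D; fh[i] <- p$f
  }
  expect_lt(abs(median(Dh) - 1.4e-3) / 1.4e-3, 0.05)
  expect_lt(abs(median(fh) - 0.08), 0.05)
  expect_true(all(fh >= 0 & fh <= 1))
})
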