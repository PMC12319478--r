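# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Mean of a Rician magnitude |nu + n_r + i n_i|, n ~ N(0, sigma^2) per channel,
# by direct numerical integration of the Rician density.
rician_mean_numeric <- function(nu, sigma) {
  integrand <- function(x) {
    # x/sigma^2 * exp(-(x^2+nu^2)/(2 sigma^2)) * I0(x nu / sigma^2) * x,
    # with the exponentially scaled Bessel to avoid overflow
    arg <- x * nu / sigma^2
    x^2 / sigma^2 * exp(-(x - nu)^2 / (2 * sigma^2)) * besselI(arg, 0, expon.scaled = TRUE)
  }
  stats::integrate(integrand, 0, nu + 12 * sigma, rel.tol = 1e-10)$value
}

# Exact least squares of log-signal against b (the high-b stage oracle).
ols_loglinear <- function(b, S) {
  X <- cbind(1, b)
  beta <- solve(crossprod(X), crossprod(X, log(S)))
  list(intercept = beta[1L], slope = beta[2L])
}

# Generic 1-parameter monoexponential least-squares oracle via golden-section
# minimization of the exact SSE.
adc_oracle <- function(b, y, interval = c(0, 0.02)) {
  stats::optimize(function(a) sum((y - exp(-b * a))^2),
                  interval = interval, tol = 1e-14)$minimum
}

# Unconstrained full 3-parameter biexponential fit from multiple starts
# (independent check of the segmented fit on noiseless data).
biexp_oracle <- function(b, y) {
  best <- NULL
  for (f0 in c(0.02, 0.1, 0.3)) for (ds0 in c(5e-3, 2e-2, 1e-1)) {
    fit <- try(minpack.lm::nls.lm(
      par = c(f = f0, D = 1e-3, Ds = ds0),
      lower = c(0, 1e-6, 1e-6), upper = c(1, 1e-2, 1),
      fn = function(p) y - (p[1] * exp(-b * p[3]) + (1 - p[1]) * exp(-b * p[2]))),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  p <- as.list(best$par)
  # the unconstrained model is symmetric under (f, D, Ds) -> (1-f, Ds, D);
  # canonicalize so the slow coefficient is reported as D
  if (p$D > p$Ds) p <- list(f = 1 - p$f, D = p$Ds, Ds = p$D)
  p
}

# Per-event-time tabulation of the two-group log-rank statistic
# (hypergeometric variance, ties pooled).
logrank_oracle <- function(time, event, group) {
  g <- unique(group)
  stopifnot(length(g) == 2L)
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (tk in ts) {
    at_risk <- time >= tk
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g[1L])
    d <- sum(time == tk & event == 1)
    d1 <- sum(time == tk & event == 1 & group == g[1L])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V == 0) return(list(chisq = 0, O = O, E = E))
  list(chisq = (O - E)^2 / V, O = O, E = E)
}

# Hand product-limit estimator.
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n)
    out[i] <- s
  }
  data.frame(time = ts, surv = out)
}

# Noiseless series on the acquisition protocol (5 x b=0 + 13 b-values).
protocol_series <- function(D, Dstar, f, S0 = 1, n_b0 = 5) {
  b <- c(rep(0, n_b0), default_bvalues())
  simulate_ivim_signal(ivim_ground_truth(D, Dstar, f, S0), b)
}

# Six-metabolite amplitude profile used in the MRS recovery tests
# (combination-arm day-6 ratio pattern relative to tCr = 1).
profile_amplitudes <- function() {
  c(tCho = 1.59, NAA = 1.28, Glx = 2.0, LipLac = 1.82, tCr = 1.0, `mI+Gly` = 0.90)
}
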