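#' Estimate the noise standard deviation of an FID
#'
#' Per-channel SD of the real and imaginary parts over the trailing fraction
#' of the record, where metabolite signal has decayed.
#'
#' @param fid a [new_fid()] object.
#' @param tail_frac fraction of trailing samples used (default 0.1).
#' @return numeric noise SD.
#' @export
estimate_noise_sigma <- function(fid, tail_frac = 0.10) {
  n <- length(fid$samples)
  idx <- seq.int(from = max(1L, floor(n * (1 - tail_frac)) + 1L), to = n)
  tail <- fid$samples[idx]
  stats::sd(c(Re(tail) - mean(Re(tail)), Im(tail) - mean(Im(tail))))
}

# design matrix of unit-amplitude basis signals under shared nuisance
# (df: global shift Hz, dlw: global broadening Hz, phi: zero-order phase)
.basis_design <- function(basis, metabs, t, lw0, f0, ppm_ref, df, dlw, phi) {
  g <- exp(-pi * dlw * t) * exp(1i * (2 * pi * df * t + phi))
  B <- sapply(metabs, function(m) {
    .basis_signal(basis, m, t, lw0, f0, ppm_ref) * g
  })
  matrix(B, nrow = length(t))
}

#' Time-domain linear-combination fit of metabolite amplitudes
#'
#' Least-squares fit of
#' `sum_m a_m B_m(t) * exp(-pi*dlw*t) * exp(i(2*pi*df*t + phi))` to a
#' water-removed FID, with nonnegative amplitudes `a_m` and three shared
#' nuisance parameters: global frequency shift `df` (Hz), global extra
#' broadening `dlw` (Hz) and zero-order phase `phi`. The nuisance parameters
#' are optimized by Levenberg-Marquardt with the amplitudes profiled out by
#' nonnegative least squares at every step (variable projection).
#'
#' Per-amplitude Cramer-Rao lower bounds are computed from the Fisher
#' information (analytic Jacobian of all amplitude + nuisance parameters at
#' the optimum, noise variance from `noise_sigma`).
#'
#' @param fid water-removed [new_fid()].
#' @param basis basis table ([default_basis()]).
#' @param noise_sigma per-channel noise SD; when `NULL`, estimated from the
#'   trailing 10% of samples via [estimate_noise_sigma()].
#' @param lw0 linewidth (Hz) at which the basis functions are synthesized.
#' @param df_bounds,dlw_bounds,phi_bounds box bounds of the nuisance
#'   parameters.
#' @return data.frame of class `metabolite_estimates` with columns
#'   `metabolite`, `amplitude`, `crlb`, `crlb_fraction`, `accepted` (NA until
#'   [crlb_filter()] is applied); attributes `nuisance` (df, dlw, phi),
#'   `sigma`, `converged`.
#' @export
fit_basis <- function(fid, basis = default_basis(), noise_sigma = NULL,
                      lw0 = 12,
                      df_bounds = c(-30, 30),
                      dlw_bounds = c(-8, 50),
                      phi_bounds = c(-pi, pi)) {
  stopifnot(inherits(fid, "fid"))
  t <- fid_time(fid)
  metabs <- unique(basis$metabolite)
  y <- c(Re(fid$samples), Im(fid$samples))
  sigma <- noise_sigma %||% estimate_noise_sigma(fid)

  nnls_amp <- function(p) {
    B <- .basis_design(basis, metabs, t, lw0, fid$transmitter_mhz, fid$ppm_ref,
                       p[1L], p[2L], p[3L])
    A <- rbind(Re(B), Im(B))
    a <- tryCatch(pracma::lsqnonneg(A, y)$x, error = function(e) NULL)
    if (is.null(a)) a <- pmax(qr.solve(A, y), 0)
    list(a = a, A = A)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(df = 0, dlw = 0, phi = 0),
      lower = c(df_bounds[1L], dlw_bounds[1L], phi_bounds[1L]),
      upper = c(df_bounds[2L], dlw_bounds[2L], phi_bounds[2L]),
      fn = function(p) { s <- nnls_amp(p); y - s$A %*% s$a },
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  converged <- !is.null(fit) && fit$info %in% 1:4
  p <- if (converged) fit$par else c(df = 0, dlw = 0, phi = 0)
  sol <- nnls_amp(p)
  a <- sol$a

  # Fisher information with analytic Jacobian at the optimum
  B <- .basis_design(basis, metabs, t, lw0, fid$transmitter_mhz, fid$ppm_ref,
                     p[[1L]], p[[2L]], p[[3L]])
  model <- as.vector(B %*% a)
  Jc <- cbind(B,
              2i * pi * t * model,   # d/d df
              -pi * t * model,       # d/d dlw
              1i * model)            # d/d phi
  J <- rbind(Re(Jc), Im(Jc))
  FI <- crossprod(J) / sigma^2
  cov <- tryCatch(solve(FI), error = function(e) pracma::pinv(FI))
  crlb <- sqrt(pmax(diag(cov)[seq_along(metabs)], 0))

  out <- data.frame(metabolite = metabs, amplitude = a, crlb = crlb,
                    crlb_fraction = ifelse(a > 0, crlb / a, Inf),
                    accepted = NA, stringsAsFactors = FALSE)
  if (!converged) out$accepted <- FALSE
  attr(out, "nuisance") <- as.list(p)
  attr(out, "sigma") <- sigma
  attr(out, "converged") <- converged
  class(out) <- c("metabolite_estimates", "data.frame")
  out
}

#' Fit the unsuppressed water resonance
#'
#' Single damped complex exponential fit
#' `c * exp(-pi*d*t) * exp(2i*pi*f*t)` (complex amplitude `c` profiled out in
#' closed form; frequency and damping optimized by Levenberg-Marquardt, with
#' the starting frequency at the magnitude-spectrum maximum). Returns the
#' water amplitude used for water-referenced scaling.
#'
#' @param fid unsuppressed-water [new_fid()].
#' @return list with `amplitude`, `freq_hz`, `damping_hz`, `phase`,
#'   `converged`.
#' @export
fit_water_reference <- function(fid) {
  stopifnot(inherits(fid, "fid"))
  x <- fid$samples
  if (sum(Mod(x)^2) == 0) {
    return(list(amplitude = NA_real_, freq_hz = NA_real_, damping_hz = NA_real_,
                phase = NA_real_, converged = FALSE))
  }
  t <- fid_time(fid)
  sp <- fid_spectrum(fid)
  f_init <- sp$hz[which.max(Mod(sp$spec))]
  camp <- function(p) {
    e <- exp((-pi * p[2L] + 2i * pi * p[1L]) * t)
    sum(Conj(e) * x) / sum(Mod(e)^2)
  }
  resid <- function(p) {
    e <- exp((-pi * max(p[2L], 0) + 2i * pi * p[1L]) * t)
    r <- x - camp(c(p[1L], max(p[2L], 0))) * e
    c(Re(r), Im(r))
  }
  fit <- minpack.lm::nls.lm(par = c(f = f_init, d = 10), fn = resid,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  p[2L] <- max(p[2L], 0)
  cc <- camp(p)
  list(amplitude = Mod(cc), freq_hz = unname(p[1L]), damping_hz = unname(p[2L]),
       phase = Arg(cc), converged = fit$info %in% 1:4)
}

#' Water-relaxation scaling parameters
#'
#' Relaxation defaults are the 9.4 T rat-brain literature values used for this
#' model: T1_water = 2097 ms, T2_water = 42 ms; the sequence defaults are
#' TR = 2000 ms, TE = 16.5 ms.
#'
#' @param water_amplitude fitted unsuppressed-water amplitude.
#' @param TR repetition time, ms.
#' @param TE echo time, ms.
#' @param T1_water,T2_water water relaxation times, ms.
#' @return object of class `water_scaling_params`.
#' @export
water_scaling_params <- function(water_amplitude, TR = 2000, TE = 16.5,
                                 T1_water = 2097, T2_water = 42) {
  stopifnot(water_amplitude > 0, TR > 0, TE > 0, T1_water > 0, T2_water > 0)
  structure(list(water_amplitude = water_amplitude, TR = TR, TE = TE,
                 T1_water = T1_water, T2_water = T2_water),
            class = "water_scaling_params")
}

#' Relaxation correction factor for water referencing
#'
#' `(1 - exp(-TR / T1_water)) * exp(-TE / T2_water)`: the fraction of the
#' fully relaxed water signal observed at the sequence's TR and TE.
#'
#' @param params a [water_scaling_params()] (the `water_amplitude` field is
#'   ignored here).
#' @return numeric correction factor in (0, 1].
#' @export
water_correction_factor <- function(params) {
  (1 - exp(-params$TR / params$T1_water)) * exp(-params$TE / params$T2_water)
}

#' Water-referenced metabolite level
#'
#' Scales a fitted metabolite amplitude by the relaxation-corrected
#' unsuppressed water amplitude:
#' `scaled = amplitude / (water_amplitude * correction) * ref_const`.
#' `ref_const` is an arbitrary-unit reference constant (default 1); no
#' absolute molar calibration is attempted.
#'
#' @param amplitude fitted metabolite amplitude.
#' @param params a [water_scaling_params()].
#' @param ref_const reference constant, arbitrary units.
#' @return scaled level, arbitrary units.
#' @export
water_scale <- function(amplitude, params, ref_const = 1) {
  stopifnot(inherits(params, "water_scaling_params"))
  amplitude / (params$water_amplitude * water_correction_factor(params)) * ref_const
}

#' Cramer-Rao lower-bound quality filter
#'
#' Flags estimates as accepted when `CRLB / amplitude < threshold` (default
#' 20%); nonpositive amplitudes are always rejected.
#'
#' @param estimates a `metabolite_estimates` data.frame from [fit_basis()].
#' @param threshold relative CRLB threshold.
#' @return the estimates with the `accepted` column filled.
#' @export
crlb_filter <- function(estimates, threshold = 0.20) {
  stopifnot(is.data.frame(estimates), all(c("amplitude", "crlb") %in% names(estimates)))
  if (any(estimates$crlb < 0, na.rm = TRUE)) stop("CRLB must be >= 0", call. = FALSE)
  estimates$accepted <- estimates$amplitude > 0 &
    is.finite(estimates$crlb) &
    (estimates$crlb / estimates$amplitude) < threshold
  if (isFALSE(attr(estimates, "converged"))) estimates$accepted <- FALSE
  estimates
}

#' Metabolite ratio table
#'
#' Ratios to total creatine (plus tCho/NAA): tCho/tCr, tCho/NAA, mI/tCr,
#' Lip+Lac/tCr, Glx/tCr. A ratio is valid only when both constituents are
#' accepted by the CRLB filter and the denominator amplitude is positive. The
#' 3.56 ppm resonance is fitted as "mI+Gly" and reported as mI.
#'
#' @param estimates filtered `metabolite_estimates` (run [crlb_filter()]
#'   first).
#' @return data.frame with columns `ratio`, `value`, `valid`.
#' @export
compute_ratios <- function(estimates) {
  stopifnot(is.data.frame(estimates))
  if (all(is.na(estimates$accepted))) {
    stop("run crlb_filter() before compute_ratios()", call. = FALSE)
  }
  get <- function(m) {
    i <- match(m, estimates$metabolite)
    if (is.na(i)) list(a = NA_real_, ok = FALSE)
    else list(a = estimates$amplitude[i], ok = isTRUE(estimates$accepted[i]))
  }
  defs <- list(`tCho/tCr` = c("tCho", "tCr"),
               `tCho/NAA` = c("tCho", "NAA"),
               `mI/tCr` = c("mI+Gly", "tCr"),
               `Lip+Lac/tCr` = c("LipLac", "tCr"),
               `Glx/tCr` = c("Glx", "tCr"))
  rows <- lapply(names(defs), function(nm) {
    num <- get(defs[[nm]][1L]); den <- get(defs[[nm]][2L])
    valid <- num$ok && den$ok && is.finite(den$a) && den$a > 0
    data.frame(ratio = nm,
               value = if (valid) num$a / den$a else NA_real_,
               valid = valid, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
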