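#' Diffusion-weighted signal series for one voxel or ROI
#'
#' @param b numeric b-values, s/mm^2.
#' @param S signal intensities, same length as `b`.
#' @param S0 reference signal at b = 0; when `NULL`, taken as the arithmetic
#'   mean of `S[b == 0]`.
#' @return object of class `dwi_series`.
#' @export
dwi_series <- function(b, S, S0 = NULL) {
  if (length(b) != length(S)) stop("b and S must have the same length", call. = FALSE)
  if (any(b < 0)) stop("negative b-values are not allowed", call. = FALSE)
  if (is.null(S0)) {
    if (!any(b == 0)) stop("S0 must be given when no b = 0 sample is present", call. = FALSE)
    S0 <- mean(S[b == 0])
  }
  structure(list(b = as.numeric(b), S = as.numeric(S), S0 = as.numeric(S0)),
            class = "dwi_series")
}

#' Configuration of the segmented IVIM fit
#'
#' Defaults follow the acquisition-matched analysis: the high-b stage uses
#' b-values strictly above 200 s/mm^2 (with the shipped protocol that is
#' \{230, 350, 570, 840, 1120, 1460\}), the pseudo-diffusion initial value is
#' 0.01 mm^2/s, and bounds cover physiologic brain ranges.
#'
#' @param high_b_threshold s/mm^2; the linear stage uses b strictly above this.
#' @param dstar_init initial pseudo-diffusion value, mm^2/s.
#' @param d_bounds length-2 bounds on D, mm^2/s.
#' @param dstar_max upper bound on D* (lower bound is the fitted D), mm^2/s.
#' @param f_bounds length-2 bounds on the perfusion fraction.
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @param ftol cost tolerance of the nonlinear stage.
#' @param signal_floor relative floor: signals <= `signal_floor * S0` are
#'   clipped before log transforms and the voxel flagged.
#' @return object of class `ivim_fit_config`.
#' @export
ivim_fit_config <- function(high_b_threshold = 200,
                            dstar_init = 0.01,
                            d_bounds = c(1e-5, 5e-3),
                            dstar_max = 0.5,
                            f_bounds = c(0, 1),
                            max_iter = 200L,
                            ftol = 1e-10,
                            signal_floor = 1e-6) {
  stopifnot(d_bounds[1] < d_bounds[2], f_bounds[1] < f_bounds[2])
  structure(list(high_b_threshold = high_b_threshold, dstar_init = dstar_init,
                 d_bounds = d_bounds, dstar_max = dstar_max, f_bounds = f_bounds,
                 max_iter = as.integer(max_iter), ftol = ftol,
                 signal_floor = signal_floor),
            class = "ivim_fit_config")
}

# clip signals for log transforms; returns list(y, clipped)
.clip_log_signal <- function(S, S0, floor_frac) {
  floor_val <- floor_frac * S0
  clipped <- S <= floor_val
  list(y = pmax(S, floor_val), clipped = any(clipped))
}

.na_ivim <- function(ADC = NA_real_) {
  structure(list(D = NA_real_, Dstar = NA_real_, f = NA_real_, ADC = ADC,
                 Sint = NA_real_, converged = FALSE, residual_norm = NA_real_),
            class = "ivim_params")
}

#' Monoexponential ADC estimate over all b-values
#'
#' Nonlinear least squares of `S_b / S0 = exp(-b * ADC)` over every b-value,
#' b = 0 included; the log-linear slope provides the starting value. The
#' apparent diffusion coefficient deliberately conflates tissue diffusion and
#' perfusion.
#'
#' @param series a [dwi_series()].
#' @param cfg an [ivim_fit_config()].
#' @return list with `ADC` (mm^2/s), `converged`, `residual_norm`.
#' @export
fit_monoexp_adc <- function(series, cfg = ivim_fit_config()) {
  stopifnot(inherits(series, "dwi_series"))
  b <- series$b; S <- series$S; S0 <- series$S0
  if (length(unique(b)) < 2L || !is.finite(S0) || S0 <= 0 || all(S == 0)) {
    return(list(ADC = NA_real_, converged = FALSE, residual_norm = NA_real_))
  }
  y <- S / S0
  cl <- .clip_log_signal(y, 1, cfg$signal_floor)
  init <- -stats::coef(stats::lm(log(cl$y) ~ b))[[2L]]
  if (!is.finite(init)) init <- 1e-3
  res <- minpack.lm::nls.lm(
    par = c(ADC = init),
    fn = function(p) y - exp(-b * p[[1L]]),
    control = minpack.lm::nls.lm.control(maxiter = cfg$max_iter, ftol = cfg$ftol))
  list(ADC = unname(res$par[[1L]]),
       converged = res$info %in% 1:4,
       residual_norm = sqrt(sum(res$fvec^2)))
}

#' High-b log-linear stage of the segmented IVIM fit
#'
#' Above the threshold the perfusion term `f exp(-b D*)` is negligible and the
#' signal is approximately monoexponential, so ordinary least squares of
#' `ln(S_b)` against b gives `D = -slope`; the back-extrapolated intercept
#' `Sint = exp(intercept)` yields the perfusion-fraction initial value
#' `f_init = 1 - Sint / S0`, clipped to [0, 1].
#'
#' @inheritParams fit_monoexp_adc
#' @return list with `D`, `Sint`, `f_init`, `converged`, `clipped`.
#' @export
fit_high_b_linear <- function(series, cfg = ivim_fit_config()) {
  stopifnot(inherits(series, "dwi_series"))
  sel <- series$b > cfg$high_b_threshold
  b <- series$b[sel]; S <- series$S[sel]
  if (length(unique(b)) < 2L || !is.finite(series$S0) || series$S0 <= 0) {
    return(list(D = NA_real_, Sint = NA_real_, f_init = NA_real_,
                converged = FALSE, clipped = FALSE))
  }
  cl <- .clip_log_signal(S, series$S0, cfg$signal_floor)
  co <- stats::coef(stats::lm(log(cl$y) ~ b))
  D <- -co[[2L]]
  Sint <- exp(co[[1L]])
  f_init <- min(max(1 - Sint / series$S0, 0), 1)
  list(D = D, Sint = Sint, f_init = f_init,
       converged = is.finite(D), clipped = cl$clipped)
}

#' Segmented (two-stage) IVIM fit
#'
#' Stage 1: [fit_high_b_linear()] estimates D and the perfusion-fraction
#' starting value from b-values above the threshold. Stage 2: Levenberg-
#' Marquardt least squares of the full biexponential model over ALL b-values
#' (b = 0 included) with D frozen at its stage-1 value; free parameters
#' `(f, D*)` start at `(f_init, dstar_init)` under box bounds
#' `f` in `f_bounds`, `D*` in `[D, dstar_max]`. The monoexponential ADC is
#' fitted alongside and returned in the same parameter set.
#'
#' @inheritParams fit_monoexp_adc
#' @return object of class `ivim_params`: fields `D`, `Dstar`, `f`, `ADC`
#'   (all mm^2/s except dimensionless `f`), `Sint`, `converged`,
#'   `residual_norm`. Non-convergence yields `converged = FALSE` with NA
#'   parameters rather than an error.
#' @export
fit_segmented_ivim <- function(series, cfg = ivim_fit_config()) {
  stopifnot(inherits(series, "dwi_series"))
  adc <- fit_monoexp_adc(series, cfg)
  s1 <- fit_high_b_linear(series, cfg)
  if (!isTRUE(s1$converged)) return(.na_ivim(adc$ADC))
  D <- min(max(s1$D, cfg$d_bounds[1L]), cfg$d_bounds[2L])
  y <- series$S / series$S0
  b <- series$b
  dstar_init <- max(cfg$dstar_init, D)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(f = s1$f_init, Dstar = dstar_init),
      lower = c(cfg$f_bounds[1L], D),
      upper = c(cfg$f_bounds[2L], cfg$dstar_max),
      fn = function(p) y - (p[[1L]] * exp(-b * p[[2L]]) + (1 - p[[1L]]) * exp(-b * D)),
      control = minpack.lm::nls.lm.control(maxiter = cfg$max_iter, ftol = cfg$ftol)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4)) return(.na_ivim(adc$ADC))
  structure(list(D = D, Dstar = unname(fit$par[["Dstar"]]),
                 f = unname(fit$par[["f"]]), ADC = adc$ADC, Sint = s1$Sint,
                 converged = TRUE, residual_norm = sqrt(sum(fit$fvec^2))),
            class = "ivim_params")
}

#' @export
print.ivim_params <- function(x, ...) {
  cat(sprintf("IVIM fit: D = %.4g mm2/s, D* = %.4g mm2/s, f = %.3f, ADC = %.4g mm2/s (%s)\n",
              x$D, x$Dstar, x$f, x$ADC,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}
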