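#' Specification of a synthetic PRESS acquisition
#'
#' Parameters of a simulated single-voxel 1H FID: 2048 complex points at
#' 4401 Hz spectral width by default, matching the 9.4 T PRESS protocol the
#' package emulates. Metabolites are parametric Lorentzian line groups from a
#' basis table; residual water is a single Lorentzian at 4.7 ppm (plus an
#' optional frequency offset); noise is additive complex Gaussian in the time
#' domain.
#'
#' @param n_points number of complex samples.
#' @param spectral_width Hz.
#' @param transmitter_mhz transmitter frequency, MHz (default 400, 1H at 9.4 T).
#' @param amplitudes named numeric vector of metabolite amplitudes (arbitrary
#'   units); names must exist in the basis table.
#' @param linewidths Hz; scalar applied to all metabolites or a named vector.
#' @param water_amplitude amplitude of the residual water line.
#' @param water_offset_hz frequency offset of water from 4.7 ppm, Hz.
#' @param water_linewidth Hz.
#' @param noise_sigma per-channel (real/imaginary) noise SD.
#' @param basis basis table, see [default_basis()].
#' @param ppm_ref ppm at zero offset.
#' @param seed integer seed; mandatory when `noise_sigma > 0`.
#' @return object of class `spectrum_spec`.
#' @export
spectrum_spec <- function(n_points = 2048L,
                          spectral_width = 4401,
                          transmitter_mhz = 400,
                          amplitudes = c(tCho = 0, NAA = 0, Glx = 0,
                                         LipLac = 0, tCr = 0, `mI+Gly` = 0),
                          linewidths = 12,
                          water_amplitude = 0,
                          water_offset_hz = 0,
                          water_linewidth = 25,
                          noise_sigma = 0,
                          basis = default_basis(),
                          ppm_ref = 4.7,
                          seed = NULL) {
  stopifnot(n_points > 0, spectral_width > 0, transmitter_mhz > 0)
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  unknown <- setdiff(names(amplitudes), unique(basis$metabolite))
  if (length(unknown)) {
    stop("amplitudes name(s) not in basis: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(list(n_points = as.integer(n_points), spectral_width = spectral_width,
                 transmitter_mhz = transmitter_mhz, amplitudes = amplitudes,
                 linewidths = linewidths, water_amplitude = water_amplitude,
                 water_offset_hz = water_offset_hz, water_linewidth = water_linewidth,
                 noise_sigma = noise_sigma, basis = basis, ppm_ref = ppm_ref,
                 seed = seed),
            class = "spectrum_spec")
}

# noiseless time-domain signal of one metabolite (unit amplitude)
.basis_signal <- function(basis, metab, t, lw, transmitter_mhz, ppm_ref) {
  rows <- basis[basis$metabolite == metab, , drop = FALSE]
  sig <- complex(length.out = length(t))
  for (k in seq_len(nrow(rows))) {
    df <- ppm_to_hz(rows$ppm[k], transmitter_mhz, ppm_ref)
    sig <- sig + rows$rel_amp[k] * exp(-pi * lw * t) * exp(2i * pi * df * t)
  }
  sig
}

#' Simulate a PRESS free induction decay
#'
#' Builds the complex time-domain signal
#' `sum_m a_m B_m(t) + water(t) + noise(t)`, where each basis function `B_m` is
#' a fixed-position Lorentzian line group damped at the requested linewidth,
#' water is a Lorentzian at 4.7 ppm (plus `water_offset_hz`), and the noise is
#' i.i.d. complex Gaussian. Errors if any requested resonance falls outside
#' the spectral window.
#'
#' @param spec a [spectrum_spec()].
#' @return a [new_fid()] object.
#' @export
simulate_fid <- function(spec) {
  stopifnot(inherits(spec, "spectrum_spec"))
  dwell <- 1 / spec$spectral_width
  t <- (seq_len(spec$n_points) - 1) * dwell
  used <- names(spec$amplitudes)[spec$amplitudes > 0]
  offsets <- c(ppm_to_hz(spec$basis$ppm[spec$basis$metabolite %in% used],
                         spec$transmitter_mhz, spec$ppm_ref),
               if (spec$water_amplitude > 0) spec$water_offset_hz)
  if (length(offsets) && max(abs(offsets)) >= spec$spectral_width / 2) {
    stop("spectral width too small to contain the requested resonance offsets",
         call. = FALSE)
  }
  sig <- complex(length.out = spec$n_points)
  for (m in names(spec$amplitudes)) {
    a <- spec$amplitudes[[m]]
    if (a == 0) next
    lw <- if (length(spec$linewidths) == 1L) spec$linewidths else spec$linewidths[[m]]
    sig <- sig + a * .basis_signal(spec$basis, m, t, lw,
                                   spec$transmitter_mhz, spec$ppm_ref)
  }
  if (spec$water_amplitude > 0) {
    sig <- sig + spec$water_amplitude *
      exp(-pi * spec$water_linewidth * t) * exp(2i * pi * spec$water_offset_hz * t)
  }
  if (spec$noise_sigma > 0) {
    if (is.null(spec$seed)) stop("seed is mandatory when noise_sigma > 0", call. = FALSE)
    sig <- sig + local_seed(spec$seed, {
      complex(real = stats::rnorm(spec$n_points, sd = spec$noise_sigma),
              imaginary = stats::rnorm(spec$n_points, sd = spec$noise_sigma))
    })
  }
  new_fid(sig, dwell, spec$transmitter_mhz, spec$ppm_ref)
}
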