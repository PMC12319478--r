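#' Convert chemical shift (ppm) to frequency offset (Hz)
#'
#' Offsets are relative to the transmitter, which is assumed on-resonance with
#' water at `ppm_ref` (4.7 ppm). Positive offsets correspond to higher ppm.
#'
#' @param ppm chemical shift values, ppm.
#' @param transmitter_mhz transmitter frequency, MHz (400 for 1H at 9.4 T).
#' @param ppm_ref reference ppm at zero offset (water).
#' @return offsets in Hz.
#' @export
ppm_to_hz <- function(ppm, transmitter_mhz, ppm_ref = 4.7) {
  (ppm - ppm_ref) * transmitter_mhz
}

#' @rdname ppm_to_hz
#' @param hz frequency offsets, Hz.
#' @export
hz_to_ppm <- function(hz, transmitter_mhz, ppm_ref = 4.7) {
  ppm_ref + hz / transmitter_mhz
}

#' Default metabolite basis table
#'
#' The six resonance groups reported for intracranial tumors in this model,
#' each as one or more Lorentzian lines at fixed ppm positions with fixed
#' relative amplitudes (summing to 1 per metabolite): total choline (tCho,
#' 3.2 ppm), N-acetylaspartate (NAA, 2.01 ppm), glutamate + glutamine (Glx,
#' 2.35 and 3.74 ppm), lipid + lactate (LipLac, 1.3 and 0.9 ppm), total
#' creatine (tCr, 3.03 ppm) and myo-inositol + glycine (mI+Gly, 3.56 ppm).
#' Relative line amplitudes within the multi-line groups are a package
#' convention (no J-evolution is modelled).
#'
#' @return data.frame with columns `metabolite`, `ppm`, `rel_amp`.
#' @export
default_basis <- function() {
  data.frame(
    metabolite = c("tCho", "NAA", "Glx", "Glx", "LipLac", "LipLac", "tCr", "mI+Gly"),
    ppm        = c(3.20,   2.01,  2.35,  3.74,  1.30,     0.90,     3.03,  3.56),
    rel_amp    = c(1.0,    1.0,   0.6,   0.4,   0.7,      0.3,      1.0,   1.0),
    stringsAsFactors = FALSE)
}

#' Extended basis with additional small resonances
#'
#' Optional superset of [default_basis()] adding phosphocreatine, taurine,
#' alanine, GABA and scyllo-inositol singlets for experiments with richer
#' spectra; positions are the conventional 1H shifts.
#'
#' @return data.frame with columns `metabolite`, `ppm`, `rel_amp`.
#' @export
extended_basis <- function() {
  rbind(default_basis(),
        data.frame(metabolite = c("PCr", "Tau", "Ala", "GABA", "sI"),
                   ppm = c(3.93, 3.42, 1.47, 2.28, 3.34),
                   rel_amp = 1.0,
                   stringsAsFactors = FALSE))
}

#' Free induction decay container
#'
#' Complex time-domain MR signal with acquisition metadata. The dwell time is
#' the inverse spectral width; the ppm reference is the chemical shift at zero
#' frequency offset (water, 4.7 ppm).
#'
#' @param samples complex vector.
#' @param dwell dwell time, s.
#' @param transmitter_mhz transmitter frequency, MHz.
#' @param ppm_ref ppm at zero offset.
#' @return object of class `fid`.
#' @export
new_fid <- function(samples, dwell, transmitter_mhz, ppm_ref = 4.7) {
  samples <- as.complex(samples)
  if (any(!is.finite(Re(samples)) | !is.finite(Im(samples)))) {
    stop("FID samples must be finite", call. = FALSE)
  }
  stopifnot(dwell > 0, transmitter_mhz > 0)
  structure(list(samples = samples, dwell = dwell,
                 transmitter_mhz = transmitter_mhz, ppm_ref = ppm_ref),
            class = "fid")
}

#' Time axis of an FID (seconds, starting at 0)
#' @param fid an object of class `fid`.
#' @return numeric vector.
#' @export
fid_time <- function(fid) {
  (seq_along(fid$samples) - 1) * fid$dwell
}

#' Complex spectrum of an FID
#'
#' Discrete Fourier transform with the first time point halved (standard
#' trapezoid-consistent convention for a signal starting at t = 0), returned
#' with a monotonically increasing ppm axis.
#'
#' @param fid an object of class `fid`.
#' @return list with `ppm` (increasing), `hz`, and complex `spec`.
#' @export
fid_spectrum <- function(fid) {
  x <- fid$samples
  x[1L] <- x[1L] / 2
  n <- length(x)
  sp <- stats::fft(x)
  # reorder to frequencies -sw/2 .. sw/2
  k <- seq_len(n) - 1L
  freq <- k / (n * fid$dwell)
  freq[freq >= 1 / (2 * fid$dwell)] <- freq[freq >= 1 / (2 * fid$dwell)] - 1 / fid$dwell
  ord <- order(freq)
  list(ppm = hz_to_ppm(freq[ord], fid$transmitter_mhz, fid$ppm_ref),
       hz = freq[ord], spec = sp[ord])
}

#' @export
print.fid <- function(x, ...) {
  cat(sprintf("FID: %d complex points, dwell %.3g s (SW %.1f Hz), %.1f MHz, ref %.2f ppm\n",
              length(x$samples), x$dwell, 1 / x$dwell, x$transmitter_mhz, x$ppm_ref))
  invisible(x)
}
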