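#' Diffusion-weighting protocol of the preclinical acquisition
#'
#' The 13 nonzero b-values (s/mm^2) of the segmented-EPI spin-echo protocol the
#' package emulates, spanning 20-1460 s/mm^2. Acquisitions additionally carry
#' `n_b0` unweighted (b = 0) images that are averaged into the reference signal
#' S0 before fitting.
#'
#' @return numeric vector of 13 b-values, sorted increasing.
#' @export
default_bvalues <- function() {
  c(20, 30, 40, 50, 60, 80, 140, 230, 350, 570, 840, 1120, 1460)
}

#' Ground-truth IVIM parameter set
#'
#' Container for the biexponential intravoxel-incoherent-motion parameters of
#' one tissue compartment: tissue diffusion coefficient `D` (mm^2/s),
#' pseudo-diffusion coefficient `Dstar` (mm^2/s, capillary flow), perfusion
#' fraction `f` (fraction of voxel volume occupied by flowing blood), and
#' unattenuated signal `S0`.
#'
#' @param D tissue diffusion coefficient, mm^2/s, >= 0.
#' @param Dstar pseudo-diffusion coefficient, mm^2/s, must be >= `D`.
#' @param f perfusion fraction in [0, 1].
#' @param S0 unattenuated (b = 0) signal, > 0.
#' @return an object of class `ivim_ground_truth`.
#' @export
ivim_ground_truth <- function(D, Dstar, f, S0 = 1) {
  stopifnot(is.numeric(D), is.numeric(Dstar), is.numeric(f), is.numeric(S0))
  if (D < 0) stop("D must be >= 0", call. = FALSE)
  if (Dstar < D) stop("Dstar must be >= D", call. = FALSE)
  if (f < 0 || f > 1) stop("f must lie in [0, 1]", call. = FALSE)
  if (S0 <= 0) stop("S0 must be > 0", call. = FALSE)
  structure(list(D = D, Dstar = Dstar, f = f, S0 = S0),
            class = "ivim_ground_truth")
}

#' Noiseless biexponential IVIM signal
#'
#' Forward model of diffusion-weighted signal attenuation with an intravoxel
#' incoherent motion (perfusion) compartment:
#' \deqn{S_b = S_0 [ f e^{-b D^*} + (1 - f) e^{-b D} ]}
#' Deterministic and noiseless; use [generate_dwi_phantom()] for noisy volumes.
#'
#' @param gt an [ivim_ground_truth()] object (or a list with fields D, Dstar,
#'   f, S0).
#' @param b numeric vector of b-values, s/mm^2, all >= 0.
#' @return a [dwi_series()] with the analytic signal at each b.
#' @export
simulate_ivim_signal <- function(gt, b) {
  if (!is.numeric(b) || any(!is.finite(b))) stop("b must be finite numeric", call. = FALSE)
  if (any(b < 0)) stop("negative b-values are not allowed", call. = FALSE)
  if (!inherits(gt, "ivim_ground_truth")) {
    gt <- ivim_ground_truth(gt$D, gt$Dstar, gt$f, gt$S0 %||% 1)
  }
  S <- gt$S0 * (gt$f * exp(-b * gt$Dstar) + (1 - gt$f) * exp(-b * gt$D))
  dwi_series(b = b, S = S, S0 = gt$S0)
}

#' Specification of a digital diffusion phantom
#'
#' Geometry, compartments, acquisition protocol and noise level of a synthetic
#' 4-D DWI volume. Compartments are named binary masks with an attached
#' [ivim_ground_truth()]; masks must be pairwise disjoint. Noise is Rician
#' (magnitude of complex Gaussian) with per-channel standard deviation
#' `sigma = S0_ref / snr_b0`, where `S0_ref` is the S0 of the compartment named
#' `"tumor"` (or the first compartment). `snr_b0 = Inf` disables noise.
#'
#' @param dim integer length-3 grid size (voxels).
#' @param voxel_size in-plane voxel size, mm, length 2.
#' @param slice_thickness slice thickness, mm.
#' @param compartments named list; each element is `list(mask = <logical 3-D
#'   array>, gt = <ivim_ground_truth>)`.
#' @param bvalues nonzero b-values, s/mm^2, strictly positive and sorted.
#' @param n_b0 number of b = 0 images (averaged into S0 downstream).
#' @param snr_b0 signal-to-noise ratio of the reference S0; `Inf` = noiseless.
#' @param seed integer seed; mandatory, fully determines the phantom.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(24L, 24L, 4L),
                         voxel_size = c(0.208, 0.208),
                         slice_thickness = 1.0,
                         compartments,
                         bvalues = default_bvalues(),
                         n_b0 = 5L,
                         snr_b0 = 40,
                         seed) {
  stopifnot(length(dim) == 3L, length(voxel_size) == 2L)
  if (any(bvalues <= 0)) stop("bvalues must be strictly positive", call. = FALSE)
  if (is.unsorted(bvalues, strictly = TRUE)) stop("bvalues must be sorted increasing", call. = FALSE)
  if (!(snr_b0 > 0)) stop("snr_b0 must be > 0", call. = FALSE)
  if (n_b0 < 1L) stop("n_b0 must be >= 1", call. = FALSE)
  if (is.null(names(compartments)) || any(names(compartments) == "")) {
    stop("compartments must be a named list", call. = FALSE)
  }
  occupancy <- array(0L, dim)
  for (cp in compartments) {
    if (!identical(dim(cp$mask), as.integer(dim))) {
      stop("compartment mask dimensions must match `dim`", call. = FALSE)
    }
    occupancy <- occupancy + (cp$mask != 0)
  }
  if (any(occupancy > 1L)) stop("compartment masks overlap", call. = FALSE)
  structure(list(dim = as.integer(dim), voxel_size = voxel_size,
                 slice_thickness = slice_thickness, compartments = compartments,
                 bvalues = bvalues, n_b0 = as.integer(n_b0), snr_b0 = snr_b0,
                 seed = seed),
            class = "phantom_spec")
}

#' Ellipsoidal mask on a voxel grid
#'
#' Convenience for building phantom compartments; radii and center in voxel
#' units.
#'
#' @param dim length-3 grid size.
#' @param center length-3 center, voxel units.
#' @param radii length-3 semi-axes, voxel units.
#' @return logical 3-D array.
#' @export
ellipsoid_mask <- function(dim, center, radii) {
  stopifnot(length(dim) == 3L, length(center) == 3L, length(radii) == 3L)
  idx <- expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]), z = seq_len(dim[3]))
  inside <- ((idx$x - center[1]) / radii[1])^2 +
            ((idx$y - center[2]) / radii[2])^2 +
            ((idx$z - center[3]) / radii[3])^2 <= 1
  array(inside, dim)
}

#' Generate a 4-D DWI phantom with known ground truth
#'
#' Builds the noiseless biexponential signal of every compartment voxel via
#' [simulate_ivim_signal()], then (unless `snr_b0 = Inf`) applies Rician noise
#' channelwise: each stored magnitude is `|S + n_r + i n_i|` with
#' `n_r, n_i ~ N(0, sigma^2)`, `sigma = S0_ref / snr_b0`. Background voxels are
#' pure noise. The output contains the 4-D volume (b = 0 repeats first), the b
#' vector, the compartment masks and per-parameter ground-truth maps so that
#' recovery can be scored exactly.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `dwi` (4-D array), `b` (length = 4th dim),
#'   `masks` (named list of logical arrays), `truth` (list of 3-D maps: D,
#'   Dstar, f, S0), `sigma` (noise SD used) and `spec`.
#' @export
generate_dwi_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  b <- c(rep(0, spec$n_b0), spec$bvalues)
  nb <- length(b)
  dims <- spec$dim
  dwi <- array(0, c(dims, nb))
  truth <- list(D = array(NA_real_, dims), Dstar = array(NA_real_, dims),
                f = array(NA_real_, dims), S0 = array(NA_real_, dims))
  for (cp in spec$compartments) {
    sig <- simulate_ivim_signal(cp$gt, b)$S
    w <- which(cp$mask != 0)
    for (k in seq_len(nb)) {
      vol <- dwi[, , , k, drop = FALSE]
      vol[w] <- sig[k]
      dwi[, , , k] <- vol
    }
    truth$D[w] <- cp$gt$D
    truth$Dstar[w] <- cp$gt$Dstar
    truth$f[w] <- cp$gt$f
    truth$S0[w] <- cp$gt$S0
  }
  ref <- spec$compartments[["tumor"]] %||% spec$compartments[[1L]]
  sigma <- if (is.finite(spec$snr_b0)) ref$gt$S0 / spec$snr_b0 else 0
  if (sigma > 0) {
    dwi <- local_seed(spec$seed, {
      n <- length(dwi)
      re <- dwi + stats::rnorm(n, sd = sigma)
      im <- stats::rnorm(n, sd = sigma)
      array(sqrt(re^2 + im^2), dim(dwi))
    })
  }
  masks <- lapply(spec$compartments, function(cp) cp$mask != 0)
  list(dwi = dwi, b = b, masks = masks, truth = truth, sigma = sigma, spec = spec)
}
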