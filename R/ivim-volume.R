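#' Voxel-wise segmented IVIM fitting over a masked 4-D volume
#'
#' Applies [fit_segmented_ivim()] to every voxel inside the mask. The per-voxel
#' S0 is the arithmetic mean of the b = 0 volumes. Out-of-mask and
#' non-converged voxels carry `NA` in the output maps; the number of fit
#' failures is reported via `message()`.
#'
#' @param dwi 4-D numeric array, 4th dimension indexed by `b`.
#' @param b numeric vector of b-values, length = `dim(dwi)[4]`.
#' @param mask logical/binary 3-D array of the ROI.
#' @param cfg an [ivim_fit_config()].
#' @return list of 3-D maps `D`, `Dstar`, `f`, `ADC`, plus `converged`
#'   (logical array) and `n_failed`.
#' @export
fit_volume <- function(dwi, b, mask, cfg = ivim_fit_config()) {
  d <- dim(dwi)
  if (length(d) != 4L) stop("dwi must be a 4-D array", call. = FALSE)
  if (length(b) != d[4L]) {
    stop(sprintf("b-value count (%d) does not match 4th dimension (%d)",
                 length(b), d[4L]), call. = FALSE)
  }
  if (!identical(dim(mask), d[1:3])) stop("mask dimensions do not match dwi grid", call. = FALSE)
  dims <- d[1:3]
  maps <- list(D = array(NA_real_, dims), Dstar = array(NA_real_, dims),
               f = array(NA_real_, dims), ADC = array(NA_real_, dims))
  conv <- array(FALSE, dims)
  voxels <- which(mask != 0)
  if (length(voxels) == 0L) {
    warning("empty mask: no voxels fitted", call. = FALSE)
    return(c(maps, list(converged = conv, n_failed = 0L)))
  }
  nvox <- prod(dims)
  mat <- matrix(dwi, nrow = nvox, ncol = d[4L])  # voxel x b
  is_b0 <- b == 0
  n_failed <- 0L
  for (v in voxels) {
    S <- mat[v, ]
    S0 <- if (any(is_b0)) mean(S[is_b0]) else NA_real_
    if (!is.finite(S0) || S0 <= 0) { n_failed <- n_failed + 1L; next }
    p <- fit_segmented_ivim(dwi_series(b, S, S0 = S0), cfg)
    if (isTRUE(p$converged)) {
      maps$D[v] <- p$D; maps$Dstar[v] <- p$Dstar
      maps$f[v] <- p$f; maps$ADC[v] <- p$ADC
      conv[v] <- TRUE
    } else {
      n_failed <- n_failed + 1L
    }
  }
  message(sprintf("fit_volume: %d voxels fitted, %d failures",
                  length(voxels), n_failed))
  c(maps, list(converged = conv, n_failed = n_failed))
}

#' ROI summary of fitted parameter maps
#'
#' Mean and sample SD (n - 1) over in-mask voxels, restricted to converged
#' voxels when the map list carries a `converged` array.
#'
#' @param maps list of 3-D parameter maps (as from [fit_volume()]).
#' @param mask logical/binary 3-D ROI mask; must be nonempty.
#' @return data.frame with columns `parameter`, `mean`, `sd`, `n_voxels`,
#'   `n_excluded`.
#' @export
summarize_roi <- function(maps, mask) {
  w <- which(mask != 0)
  if (length(w) == 0L) stop("mask is empty", call. = FALSE)
  conv <- maps$converged
  params <- intersect(names(maps), c("D", "Dstar", "f", "ADC"))
  rows <- lapply(params, function(p) {
    vals <- maps[[p]][w]
    ok <- is.finite(vals)
    if (!is.null(conv)) ok <- ok & conv[w]
    v <- vals[ok]
    data.frame(parameter = p,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1L) stats::sd(v) else if (length(v) == 1L) 0 else NA_real_,
               n_voxels = length(v),
               n_excluded = length(w) - length(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tumor volume from a contoured mask
#'
#' Slice-wise areas (voxel count times in-plane voxel area) summed and
#' multiplied by the slice thickness, as in manual contouring of anatomical
#' images.
#'
#' @param mask binary 3-D array, 3rd dimension = slices.
#' @param voxel_size length-2 in-plane voxel size, mm.
#' @param slice_thickness slice thickness, mm.
#' @return list with `volume` (mm^3), `slice_areas` (mm^2 per slice),
#'   `slice_thickness`.
#' @export
compute_tumor_volume <- function(mask, voxel_size, slice_thickness) {
  stopifnot(length(dim(mask)) == 3L, length(voxel_size) == 2L)
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0, 1, FALSE, TRUE))) stop("mask must be binary", call. = FALSE)
  pix_area <- prod(voxel_size)
  areas <- apply(mask != 0, 3L, sum) * pix_area
  list(volume = sum(areas) * slice_thickness,
       slice_areas = areas,
       slice_thickness = slice_thickness)
}
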