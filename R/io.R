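#' Write a DWI phantom to NIfTI + bval sidecar
#'
#' Writes the 4-D volume as NIfTI (one volume per b, `.nii` or `.nii.gz` by
#' extension), a whitespace-separated one-line FSL-style `.bval` sidecar, each
#' compartment mask as uint8 NIfTI, and the ground-truth parameter maps as
#' float NIfTI (`{stem}_truth_D` etc.).
#'
#' @param phantom output of [generate_dwi_phantom()].
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @param gz write gzipped NIfTI.
#' @return invisibly, the path of the main volume.
#' @export
write_dwi_phantom <- function(phantom, dir, stem = "phantom", gz = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gz) ".nii.gz" else ".nii"
  vs <- phantom$spec$voxel_size
  pix <- c(vs[1L], vs[2L], phantom$spec$slice_thickness)
  wr <- function(arr, path, datatype = "float") {
    img <- RNifti::asNifti(arr)
    img <- RNifti::`pixdim<-`(img, pix)
    RNifti::writeNifti(img, path, datatype = datatype)
  }
  main <- file.path(dir, paste0(stem, ext))
  wr(phantom$dwi, main)
  writeLines(paste(phantom$b, collapse = " "),
             file.path(dir, paste0(stem, ".bval")))
  for (nm in names(phantom$masks)) {
    wr(phantom$masks[[nm]] + 0L, file.path(dir, paste0(stem, "_mask_", nm, ext)),
       datatype = "uint8")
  }
  for (p in names(phantom$truth)) {
    wr(phantom$truth[[p]], file.path(dir, paste0(stem, "_truth_", p, ext)))
  }
  invisible(main)
}

#' Read a 4-D DWI volume and its b-value sidecar
#'
#' @param nifti_path path to a `.nii` / `.nii.gz` 4-D volume.
#' @param bval_path path to a whitespace-separated one-line b-value file.
#' @return list with `dwi` (4-D array), `b` (numeric), `image` (the RNifti
#'   object, affine retained).
#' @export
read_dwi <- function(nifti_path, bval_path) {
  img <- RNifti::readNifti(nifti_path)
  b <- scan(bval_path, what = numeric(), quiet = TRUE)
  nvol <- if (length(dim(img)) == 4L) dim(img)[4L] else 1L
  if (length(b) != nvol) {
    stop(sprintf("b-value count (%d) does not match volume count (%d)",
                 length(b), nvol), call. = FALSE)
  }
  list(dwi = array(as.numeric(img), dim(img)), b = b, image = img)
}

#' Read a binary ROI mask from NIfTI
#'
#' @param path `.nii` / `.nii.gz` mask volume.
#' @return logical 3-D array.
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) > 3L) d <- d[1:3]
  array(as.numeric(img) != 0, d)
}

#' Write parameter maps as NIfTI
#'
#' One float32 file per parameter, named `{stem}_D`, `{stem}_Dstar`,
#' `{stem}_f`, `{stem}_ADC`.
#'
#' @param maps list of 3-D maps (from [fit_volume()]).
#' @param dir output directory.
#' @param stem file-name stem.
#' @param gz write gzipped NIfTI.
#' @return invisibly, the vector of paths written.
#' @export
write_parameter_maps <- function(maps, dir, stem = "ivim", gz = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gz) ".nii.gz" else ".nii"
  params <- intersect(names(maps), c("D", "Dstar", "f", "ADC"))
  paths <- vapply(params, function(p) {
    path <- file.path(dir, paste0(stem, "_", p, ext))
    arr <- maps[[p]]
    arr[!is.finite(arr)] <- 0
    RNifti::writeNifti(RNifti::asNifti(arr), path, datatype = "float")
    path
  }, character(1L))
  invisible(paths)
}

#' Write / read an FID in the package interchange format
#'
#' A JSON header (`dwell_s`, `transmitter_mhz`, `ppm_ref`, `n_points`) next to
#' a CSV body with columns `index`, `real`, `imag`. Round-trips complex
#' samples and metadata losslessly (doubles serialized at full precision).
#'
#' @param fid a [new_fid()] object.
#' @param stem path stem; writes `<stem>.json` and `<stem>.csv`.
#' @return invisibly, the stem.
#' @export
write_fid <- function(fid, stem) {
  stopifnot(inherits(fid, "fid"))
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  # %.17g guarantees bit-exact double round-trip, which jsonlite's default
  # 15-digit serialization does not
  header <- sprintf(
    '{"dwell_s":%.17g,"transmitter_mhz":%.17g,"ppm_ref":%.17g,"n_points":%d}',
    fid$dwell, fid$transmitter_mhz, fid$ppm_ref, length(fid$samples))
  writeLines(header, paste0(stem, ".json"))
  body <- data.frame(index = seq_along(fid$samples) - 1L,
                     real = sprintf("%.17g", Re(fid$samples)),
                     imag = sprintf("%.17g", Im(fid$samples)))
  utils::write.csv(body, paste0(stem, ".csv"), row.names = FALSE, quote = FALSE)
  invisible(stem)
}

#' @rdname write_fid
#' @export
read_fid <- function(stem) {
  hpath <- paste0(stem, ".json"); bpath <- paste0(stem, ".csv")
  if (!file.exists(hpath)) stop("missing header: ", hpath, call. = FALSE)
  if (!file.exists(bpath)) stop("missing body: ", bpath, call. = FALSE)
  header <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  for (field in c("dwell_s", "transmitter_mhz", "ppm_ref", "n_points")) {
    if (is.null(header[[field]])) {
      stop("FID header is missing required field: ", field, call. = FALSE)
    }
  }
  body <- utils::read.csv(bpath, colClasses = c("integer", "numeric", "numeric"))
  if (nrow(body) != header$n_points) {
    stop(sprintf("header n_points (%d) does not match body rows (%d)",
                 header$n_points, nrow(body)), call. = FALSE)
  }
  new_fid(complex(real = body$real, imaginary = body$imag),
          dwell = as.numeric(header$dwell_s),
          transmitter_mhz = as.numeric(header$transmitter_mhz),
          ppm_ref = as.numeric(header$ppm_ref))
}

#' Write / read a long-format cohort table
#'
#' CSV with columns `animal_id`, `group`, `day`, `metric`, `value`,
#' `survival_time`, `event`.
#'
#' @param table cohort table data.frame.
#' @param path CSV path.
#' @return invisibly the path (write) / the table (read).
#' @export
write_cohort <- function(table, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "day", "metric", "value",
            "survival_time", "event")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols)) {
    stop("cohort CSV is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  class(tbl) <- c("cohort_table", "data.frame")
  tbl
}

#' Read and validate a run configuration (YAML or JSON)
#'
#' Strict top-level schema: keys outside
#' \{seed, out_dir, phantom, spectrum, cohort, ivim, mrs, stats\} are
#' rejected, and `seed` is mandatory (every stochastic stage derives from it).
#'
#' @param path YAML (or JSON, which YAML subsumes) configuration file.
#' @return named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("seed", "out_dir", "phantom", "spectrum", "cohort", "ivim",
               "mrs", "stats")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(cfg$seed)) stop("config must set `seed`", call. = FALSE)
  structure(cfg, class = c("run_config", "list"))
}
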