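#' End-to-end demonstration pipeline
#'
#' Runs the four stages on one configuration: (1) simulate a DWI phantom, a
#' water-suppressed PRESS FID with residual water, an unsuppressed water FID,
#' and a longitudinal treatment cohort; (2) voxel-wise segmented IVIM fitting
#' of the phantom tumor with ROI summaries and tumor volumetry; (3) the MRS
#' chain (HLSVD water removal, apodization/zero-fill, basis fitting, CRLB
#' filter, water scaling, ratio table); (4) the cohort statistics of
#' [run_study()]. Every random draw derives from `config$seed`, so two runs
#' with the same configuration produce byte-identical output files.
#'
#' @param config a `run_config` list (see [read_run_config()]) or a path to a
#'   YAML/JSON configuration; must carry `seed`, may carry `out_dir` and
#'   per-stage overrides (`phantom`: dim, snr_b0, tumor/brain parameters;
#'   `spectrum`: amplitudes, snr, water_amplitude; `cohort`: n_per_group,
#'   rho; `mrs`: lb, n_out, model_order, crlb_threshold; `stats`:
#'   baseline_day, m).
#' @param out_dir overrides `config$out_dir`.
#' @return list with elements `phantom_summary`, `tumor_volume`,
#'   `mrs_estimates`, `ratios`, `scaled_levels`, `study` (the [run_study()]
#'   bundle) and `paths`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$seed)) stop("config must set `seed`", call. = FALSE)
  seed <- as.integer(config$seed)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("an output directory is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sub_seed <- function(k) (seed %% 268435456L) * 8L + k

  ## -- stage 1a: DWI phantom ------------------------------------------------
  ph_cfg <- utils::modifyList(
    list(dim = c(24L, 24L, 4L), snr_b0 = 40,
         tumor = list(D = 1.4e-3, Dstar = 0.01, f = 0.08, S0 = 1),
         brain = list(D = 0.8e-3, Dstar = 0.008, f = 0.03, S0 = 0.9)),
    config$phantom %||% list())
  dims <- as.integer(ph_cfg$dim)
  tumor_mask <- ellipsoid_mask(dims, center = dims / 2 + 0.5,
                               radii = c(dims[1L] / 4, dims[2L] / 4, dims[3L] / 2.5))
  brain_mask <- ellipsoid_mask(dims, center = dims / 2 + 0.5,
                               radii = c(dims[1L] / 2.2, dims[2L] / 2.2, dims[3L])) &
                !tumor_mask
  spec <- phantom_spec(
    dim = dims,
    compartments = list(
      tumor = list(mask = tumor_mask,
                   gt = do.call(ivim_ground_truth, ph_cfg$tumor)),
      brain = list(mask = brain_mask,
                   gt = do.call(ivim_ground_truth, ph_cfg$brain))),
    snr_b0 = ph_cfg$snr_b0, seed = sub_seed(1L))
  phantom <- generate_dwi_phantom(spec)
  dwi_dir <- file.path(out_dir, "dwi")
  write_dwi_phantom(phantom, dwi_dir)

  ## -- stage 2: IVIM fitting ------------------------------------------------
  ivim_cfg <- do.call(ivim_fit_config, config$ivim %||% list())
  maps <- suppressMessages(
    fit_volume(phantom$dwi, phantom$b, phantom$masks$tumor, ivim_cfg))
  write_parameter_maps(maps, dwi_dir)
  roi <- summarize_roi(maps, phantom$masks$tumor)
  vol <- compute_tumor_volume(phantom$masks$tumor + 0, spec$voxel_size,
                              spec$slice_thickness)
  utils::write.csv(roi, file.path(dwi_dir, "roi_summary.csv"), row.names = FALSE)
  utils::write.csv(data.frame(volume_mm3 = vol$volume),
                   file.path(dwi_dir, "tumor_volume.csv"), row.names = FALSE)

  ## -- stage 1b + 3: MRS ----------------------------------------------------
  sp_cfg <- utils::modifyList(
    list(amplitudes = c(tCho = 1.59, NAA = 1.28, Glx = 2.0, LipLac = 1.82,
                        tCr = 1.0, `mI+Gly` = 0.90),
         snr = 50, water_amplitude = 100, water_ref_amplitude = 5000),
    config$spectrum %||% list())
  amps <- unlist(sp_cfg$amplitudes)
  sigma <- amps[["tCr"]] / sp_cfg$snr
  fid_ws <- simulate_fid(spectrum_spec(
    amplitudes = amps, water_amplitude = sp_cfg$water_amplitude,
    noise_sigma = sigma, seed = sub_seed(2L)))
  fid_w <- simulate_fid(spectrum_spec(
    amplitudes = amps * 0, water_amplitude = sp_cfg$water_ref_amplitude,
    noise_sigma = sigma, seed = sub_seed(3L)))
  mrs_dir <- file.path(out_dir, "mrs")
  write_fid(fid_ws, file.path(mrs_dir, "fid_suppressed"))
  write_fid(fid_w, file.path(mrs_dir, "fid_water"))

  mrs_cfg <- utils::modifyList(
    list(model_order = 25L, lb = 5, n_out = 4196L, crlb_threshold = 0.20),
    config$mrs %||% list())
  filtered <- suppressWarnings(
    hlsvd_filter(fid_ws, model_order = mrs_cfg$model_order))
  proc <- apodize_zerofill(filtered, lb = mrs_cfg$lb, n_out = mrs_cfg$n_out)
  est <- fit_basis(proc, noise_sigma = estimate_noise_sigma(fid_ws))
  est <- crlb_filter(est, threshold = mrs_cfg$crlb_threshold)
  ratios <- compute_ratios(est)
  wfit <- fit_water_reference(fid_w)
  scaled <- if (isTRUE(wfit$converged)) {
    wp <- water_scaling_params(wfit$amplitude)
    data.frame(metabolite = est$metabolite,
               scaled_level = ifelse(est$accepted,
                                     water_scale(est$amplitude, wp), NA_real_))
  }
  utils::write.csv(est, file.path(mrs_dir, "metabolites.csv"), row.names = FALSE)
  utils::write.csv(ratios, file.path(mrs_dir, "ratios.csv"), row.names = FALSE)
  if (!is.null(scaled)) {
    utils::write.csv(scaled, file.path(mrs_dir, "scaled_levels.csv"),
                     row.names = FALSE)
  }

  ## -- stage 1c + 4: cohort -------------------------------------------------
  co_args <- config$cohort %||% list()
  co_args$seed <- sub_seed(4L)
  cspec <- do.call(cohort_spec, co_args)
  cohort <- generate_cohort(cspec)
  co_dir <- file.path(out_dir, "cohort")
  write_cohort(cohort, file.path(co_dir, "cohort.csv"))
  st_cfg <- config$stats %||% list()
  study <- suppressWarnings(
    run_study(cohort, baseline_day = st_cfg$baseline_day %||% 0,
              m = st_cfg$m, out_dir = co_dir))

  list(phantom_summary = roi, tumor_volume = vol$volume,
       mrs_estimates = est, ratios = ratios, scaled_levels = scaled,
       study = study,
       paths = list(dwi = dwi_dir, mrs = mrs_dir, cohort = co_dir))
}
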