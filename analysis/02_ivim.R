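#!/usr/bin/env Rscript
# Stage 2 — segmented IVIM analysis of the simulated phantom: voxel-wise
# (D, D*, f, ADC) maps over the tumor mask, ROI summaries scored against the
# stored ground truth, tumor volumetry, and a Monte-Carlo recovery experiment
# at SNR 40. Reads results/simulated/, writes results/ivim/.

suppressPackageStartupMessages(library(ivimrs))

sim <- "results/simulated/dwi"
out <- "results/ivim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

vol <- read_dwi(file.path(sim, "phantom.nii"), file.path(sim, "phantom.bval"))
mask <- read_mask(file.path(sim, "phantom_mask_tumor.nii"))
truth_D <- 1.4e-3

maps <- fit_volume(vol$dwi, vol$b, mask)
write_parameter_maps(maps, out, "phantom")
roi <- summarize_roi(maps, mask)
utils::write.csv(roi, file.path(out, "roi_summary.csv"), row.names = FALSE)
message("ROI summary (truth: D = 1.4e-3, D* = 0.01, f = 0.08):")
print(roi)
message(sprintf("ROI mean D off truth by %.2f%%",
                100 * abs(roi$mean[roi$parameter == "D"] - truth_D) / truth_D))

tv <- compute_tumor_volume(mask + 0L, voxel_size = c(0.208, 0.208),
                           slice_thickness = 1.0)
message(sprintf("tumor volume from mask: %.2f mm^3 over %d slices",
                tv$volume, length(tv$slice_areas)))

## Monte-Carlo recovery: 1000 noisy realizations of one tumor voxel at SNR 40
b <- c(rep(0, 5), default_bvalues())
clean <- simulate_ivim_signal(ivim_ground_truth(1.4e-3, 0.01, 0.08), b)$S
set.seed(402)
reps <- t(replicate(1000, {
  S <- sqrt((clean + rnorm(length(b), sd = 1 / 40))^2 +
              rnorm(length(b), sd = 1 / 40)^2)
  p <- fit_segmented_ivim(dwi_series(b, S))
  c(D = p$D, Dstar = p$Dstar, f = p$f, ADC = p$ADC)
}))
mc <- data.frame(parameter = colnames(reps),
                 truth = c(1.4e-3, 0.01, 0.08, NA),
                 median = apply(reps, 2, median),
                 q25 = apply(reps, 2, quantile, 0.25),
                 q75 = apply(reps, 2, quantile, 0.75))
utils::write.csv(mc, file.path(out, "monte_carlo.csv"), row.names = FALSE)
message("Monte-Carlo medians at SNR 40 (1000 repetitions):")
print(mc, digits = 4)
message(sprintf("median D within %.2f%% of truth; median f within %.4f absolute",
                100 * abs(mc$median[1] - 1.4e-3) / 1.4e-3,
                abs(mc$median[3] - 0.08)))
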