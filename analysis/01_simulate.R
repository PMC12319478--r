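#!/usr/bin/env Rscript
# Stage 1 — simulate the study's raw materials with known ground truth:
# a multi-b diffusion phantom (tumor + brain compartments, Rician noise),
# a water-suppressed / unsuppressed PRESS FID pair, and the four-arm
# longitudinal cohort at the in vivo group sizes (16/14/11/11).
# Outputs land under results/simulated/.

suppressPackageStartupMessages(library(ivimrs))

out <- "results/simulated"
seed <- 20260925L

## DWI phantom: tumor (D = 1.4e-3 mm^2/s, D* = 0.01, f = 0.08) inside brain
## (D = 0.8e-3, D* = 0.008, f = 0.03), 5 x b=0 + 13 b-values, SNR 40 at b=0.
dims <- c(24L, 24L, 4L)
tumor <- ellipsoid_mask(dims, center = dims / 2 + 0.5, radii = c(6, 6, 1.6))
brain <- ellipsoid_mask(dims, center = dims / 2 + 0.5, radii = c(11, 11, 4)) & !tumor
spec <- phantom_spec(
  dim = dims,
  compartments = list(
    tumor = list(mask = tumor, gt = ivim_ground_truth(1.4e-3, 0.01, 0.08)),
    brain = list(mask = brain, gt = ivim_ground_truth(0.8e-3, 0.008, 0.03, S0 = 0.9))),
  snr_b0 = 40, seed = seed)
phantom <- generate_dwi_phantom(spec)
write_dwi_phantom(phantom, file.path(out, "dwi"), "phantom")
message(sprintf("phantom: %d tumor voxels, %d brain voxels, sigma = %.4f",
                sum(phantom$masks$tumor), sum(phantom$masks$brain), phantom$sigma))

## PRESS FIDs: combination-arm day-6 amplitude profile (relative to tCr = 1),
## residual water at 100:1 over tCr, SNR 50; plus an unsuppressed water FID.
amps <- c(tCho = 1.59, NAA = 1.28, Glx = 2.0, LipLac = 1.82, tCr = 1.0,
          `mI+Gly` = 0.90)
fid_ws <- simulate_fid(spectrum_spec(amplitudes = amps, water_amplitude = 100,
                                     noise_sigma = 1 / 50, seed = seed + 1L))
fid_w <- simulate_fid(spectrum_spec(amplitudes = amps * 0, water_amplitude = 5000,
                                    noise_sigma = 1 / 50, seed = seed + 2L))
write_fid(fid_ws, file.path(out, "mrs", "fid_suppressed"))
write_fid(fid_w, file.path(out, "mrs", "fid_water"))
message(sprintf("FIDs: %d points at %.0f Hz spectral width, water:tCr = 100:1",
                length(fid_ws$samples), 1 / fid_ws$dwell))

## Longitudinal cohort at the four-arm design, group trajectories and
## study-end survival as programmed in default_cohort_params().
cohort <- generate_cohort(cohort_spec(seed = seed + 3L))
write_cohort(cohort, file.path(out, "cohort.csv"))
sr <- unique(cohort[, c("animal_id", "group", "event")])
message("cohort: ", nrow(sr), " animals; day-6 survival by arm: ",
        paste(sprintf("%s %.0f%%", names(table(sr$group)),
                      100 * tapply(sr$event == 0, sr$group, mean)),
              collapse = ", "))
message("done: inputs written under ", out)
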