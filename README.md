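# ivimrs

Quantitative treatment-response analysis for preclinical brain-tumor MRI, built
for studies that follow a GL261 glioblastoma mouse cohort through therapy with
diffusion and spectroscopy readouts. The package implements the full
measurement chain as tested R code and pairs every stage with a synthetic
generator with known ground truth, so the estimators can be validated without
any animal data.

Three measurement models sit at the core:

* **Segmented IVIM.** Diffusion-weighted signal follows the intravoxel
  incoherent motion biexponential
  `S_b/S0 = f·exp(−b·D*) + (1−f)·exp(−b·D)`.
  A log-linear fit over b > 200 s/mm² yields the tissue diffusion coefficient
  D and, through the back-extrapolated intercept, the perfusion-fraction
  start value `f0 = 1 − S_int/S0`; a Levenberg–Marquardt fit of the full model
  over all b-values with D frozen then estimates (f, D*), with D* started at
  0.01 mm²/s. The monoexponential ADC (`S_b/S0 = exp(−b·ADC)`) is fitted
  alongside, and voxel-wise maps, ROI summaries and slice-area×thickness
  tumor volumetry complete the module.
* **MRS quantification.** PRESS FIDs (2048 points, 4401 Hz at 9.4 T) are
  water-filtered with HLSVD (Hankel SVD + linear prediction, model order 25,
  removal band 4.7 ± 0.25 ppm), apodized (5 Hz Lorentzian) and zero-filled,
  then fitted in the time domain as a nonnegative linear combination of
  metabolite line groups (tCho 3.2, NAA 2.01, Glx 2.35/3.74, Lip+Lac 1.3/0.9,
  tCr 3.03, mI+Gly 3.56 ppm) with shared shift/broadening/phase nuisance
  parameters. Cramér–Rao lower bounds from the Fisher information drive the
  CRLB/amplitude < 20% acceptance rule; levels are referenced to the fitted
  unsuppressed water signal with the relaxation correction
  `(1 − exp(−TR/T1,water))·exp(−TE/T2,water)` and reported as ratios to tCr.
* **Cohort statistics.** Per-animal percent change from baseline, one-way
  ANOVA with Bonferroni-adjusted pairwise post hoc tests per metric × day,
  Kaplan–Meier survival curves and pairwise log-rank tests across the four
  treatment arms (control, MN58b, TMZ, MN58b+TMZ; n = 16/14/11/11).

## Worked example

Fit one noisy tumor voxel at the acquisition's b-values and SNR:

```r
library(ivimrs)
b  <- c(rep(0, 5), default_bvalues())          # 5 x b=0 + 13 b-values
gt <- ivim_ground_truth(D = 1.4e-3, Dstar = 0.01, f = 0.08)
S  <- simulate_ivim_signal(gt, b)$S
set.seed(1)
S  <- sqrt((S + rnorm(18, sd = 1/40))^2 + rnorm(18, sd = 1/40)^2)  # Rician
fit_segmented_ivim(dwi_series(b, S))
#> IVIM fit: D = 0.001251 mm2/s, D* = 0.004898 mm2/s, f = 0.195, ADC = 0.001583 mm2/s (converged)
```

A single voxel at SNR 40 is noisy — this draw lands ~11% low on D and high on
f. Aggregation is what stabilizes the estimates: over 1000 such draws the
median D̂ falls within 0.1% of truth and the median f̂ within 0.006 absolute
(`analysis/02_ivim.R`), and ROI means over ~200 voxels sit within ~1% of
truth.

Quantify a synthetic spectrum through the full MRS chain:

```r
amps <- c(tCho = 1.59, NAA = 1.28, Glx = 2, LipLac = 1.82, tCr = 1, `mI+Gly` = 0.9)
fid  <- simulate_fid(spectrum_spec(amplitudes = amps, water_amplitude = 100,
                                   noise_sigma = 1/50, seed = 7))
est  <- fid |> hlsvd_filter() |> apodize_zerofill() |>
        fit_basis(noise_sigma = estimate_noise_sigma(fid)) |> crlb_filter()
compute_ratios(est)
#>         ratio     value valid
#> 1    tCho/tCr 1.5768585  TRUE
#> 2    tCho/NAA 1.2402124  TRUE
#> 3      mI/tCr 0.8988375  TRUE
#> 4 Lip+Lac/tCr 1.8063119  TRUE
#> 5     Glx/tCr 1.9900457  TRUE
```

The programmed truths are tCho/tCr = 1.59, tCho/NAA ≈ 1.24, mI/tCr = 0.90,
Lip+Lac/tCr = 1.82, Glx/tCr = 2.0 — each ratio is recovered well inside 1% at
this SNR, and all six metabolites pass the 20% CRLB rule.

## Analysis workflow

The numbered scripts under `analysis/` run the study end to end, writing
tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # phantom + FID pair + four-arm cohort
Rscript analysis/02_ivim.R      # parameter maps, ROI summary, Monte-Carlo
Rscript analysis/03_mrs.R       # metabolite estimates, ratio recovery
Rscript analysis/04_cohort.R    # percent change, ANOVA/Bonferroni, KM, log-rank
```

On the shipped configuration, stage 4 reports the combination arm with the
largest mean day-6 increase in D (+31.4% vs −10.0% in controls; ANOVA
F = 8.13, Bonferroni-adjusted combination-vs-control p = 0.0019), the lowest
day-6 rise in Lip+Lac/tCr, and 100% day-6 survival against 50% in controls
(log-rank chi-square = 7.27, p = 0.007). `run_pipeline()` exposes the same
end-to-end run as one call on a YAML config (`inst/extdata/demo_config.yaml`)
and is byte-reproducible from (config, seed).

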