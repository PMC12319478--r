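---
title: "Models and methods behind ivimrs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ivimrs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivimrs)
```

ivimrs reimplements, as a tested and reusable pipeline, the quantitative
analysis of a preclinical treatment-response study in an orthotopic GL261
glioblastoma mouse model: segmented IVIM fitting of multi-b diffusion MRI,
time-domain quantification of single-voxel ^1^H spectra, tumor volumetry, and
the cohort statistics that compare four treatment arms (saline control, the
choline-kinase-alpha inhibitor MN58b, temozolomide, and their combination)
over scans at days 0, 3 and 6. Because no raw animal data are available, the
package pairs every analysis stage with a synthetic generator that emulates
the acquisition, so that all claims about the estimators are tested against
known ground truth.

## The IVIM model and the segmented fit

Diffusion-weighted signal in perfused tissue is modelled as the biexponential

$$\frac{S_b}{S_0} = f\,e^{-b D^*} + (1 - f)\,e^{-b D},$$

where $D$ (mm²/s) is the tissue water diffusion coefficient, $D^*$ the
pseudo-diffusion coefficient of capillary blood, and $f$ the perfusion
fraction. The apparent diffusion coefficient (ADC) is the single-exponential
summary $S_b/S_0 = e^{-b\,\mathrm{ADC}}$ fitted over all b-values and
deliberately conflates both pools.

`fit_segmented_ivim()` follows the classic two-stage procedure:

1. **High-b linear stage.** For $b > 200$ s/mm² the perfusion term is
   neglected and ordinary least squares of $\ln S_b$ against $b$ gives
   $D = -\text{slope}$; the back-extrapolated intercept $S_{int}$ gives the
   perfusion-fraction start value $f_0 = 1 - S_{int}/S_0$. With the emulated
   protocol (13 b-values, 20–1460 s/mm²) the stage uses
   {230, 350, 570, 840, 1120, 1460}; the threshold is strict and
   configurable. The phrase "zero intercept" sometimes attached to this stage
   is internally inconsistent with using $S_{int}$ for $f$; the package fits
   an unconstrained intercept, which is the only reading under which $f_0$ is
   defined.
2. **Nonlinear stage.** Levenberg–Marquardt least squares
   (`minpack.lm::nls.lm`) of the full biexponential over *all* b-values
   (b = 0 included; configurable), with $D$ frozen at its stage-1 value and
   $(f, D^*)$ free, started at $(f_0, 0.01\ \text{mm}^2/\text{s})$ under box
   bounds $f \in [0, 1]$, $D^* \in [D, 0.5]$, $D \in [10^{-5}, 5\times10^{-3}]$
   mm²/s (physiologic brain ranges). Bounds are enforced natively by the
   optimizer rather than through a parameter transform. Non-convergence
   yields an `NA` sentinel, never an exception; such voxels are excluded from
   ROI summaries (which use the $n-1$ SD convention).

**Accuracy limits of the segmented estimator.** The high-b stage is exact
only in the limit where the perfusion term has fully decayed above the
threshold. At $D^* = 5\times10^{-3}$ mm²/s the residue
$f e^{-230 D^*} \approx 0.32 f$ is far from negligible: on noiseless signals
the stage-1 $D$ is biased by up to ~8% at $f = 0.2$, and since stage 2 keeps
$D$ frozen, the error propagates into $f$ and especially $D^*$ (20–30%).
This is a property of the method, not of the implementation — an exact-OLS
oracle on analytic signals reproduces the same numbers. The recovery bands
the package asserts in its green test suite are therefore restricted to the
regime where two-compartment separation actually holds: $D^* \ge 10^{-2}$
mm²/s with $f \le 0.1$, and $D^* = 5\times10^{-2}$ mm²/s up to $f = 0.3$
(D within 2%, $f$ within 0.02, $D^*$ within 20% — $D^*$ is weakly identified
throughout, hence the wide band). A deliberately stricter whole-grid check
that extends down to $D^* = 5\times10^{-3}$ is kept in the acceptance tests
and fails exactly on that slice, documenting the boundary rather than hiding
it. At $f = 0$ the model degenerates to one compartment; $D^*$ is then
unidentifiable and only $D$, $f \le 0.01$ and ADC $= D$ are asserted.

**Noise.** Phantom volumes carry Rician noise — each stored magnitude is
$|S + n_r + i\,n_i|$ with i.i.d. Gaussian channels — the standard model for
magnitude MR images; sigma is referenced to the tumor-compartment $S_0$
through `snr_b0`. At the emulated SNR of 40, Monte-Carlo recovery at the
tumor operating point ($D = 1.4\times10^{-3}$, $D^* = 0.01$, $f = 0.08$) is
median-unbiased within a few percent for $D$ and within ~0.01 absolute for
$f$; the fitted $f$ always stays in $[0,1]$ by construction. Log transforms
clip signals at $10^{-6} S_0$ to guard against non-positive noisy values.

**Volumetry.** `compute_tumor_volume()` multiplies per-slice contoured areas
by the slice thickness, the same arithmetic used on the anatomical images.

## Spectroscopy: water removal, basis fitting, CRLB

The emulated acquisition is a PRESS voxel at 9.4 T (400 MHz): 2048 complex
points at 4401 Hz spectral width, TR/TE = 2000/16.5 ms.

**HLSVD residual-water filter.** `hlsvd_filter()` models the FID as a sum of
damped complex exponentials through the state-space (HSVD/HTLS) route: an
SVD of the Hankel matrix of the leading samples (default 1024; water
dominates early samples and the extracted poles extrapolate), shift-
invariance of the signal subspace for the pole estimates, least squares
against the full record for amplitudes, and subtraction of every component
whose frequency falls in the removal band (default 4.7 ± 0.25 ppm, model
order 25). Rank-deficient Hankel matrices fall back to a smaller effective
order with a warning; growing poles ($|z| > 1.005$) are discarded as
numerically unstable under extrapolation. On a noiseless 100:1
water:metabolite pair the filter removes > 99.99% of the water energy while
perturbing the metabolite amplitude at the 10⁻¹⁴ level.

**Processing.** `apodize_zerofill()` applies Lorentzian line broadening
(default 5 Hz, adding exactly 5 Hz to every Lorentzian width) and zero-fills
to 4196 points — kept verbatim from the emulated protocol even though it is
almost certainly a typo for 4096; both are one argument away.

**Basis model.** Metabolites are parametric line groups at fixed chemical
shifts: tCho 3.2, NAA 2.01, Glx 2.35/3.74, Lip+Lac 1.3/0.9, tCr 3.03,
mI+Gly 3.56 ppm (the 3.56 ppm resonance is fitted as "mI+Gly" and reported
as mI). Relative line amplitudes inside the two-line groups (Glx 0.6/0.4,
Lip+Lac 0.7/0.3) and the 12 Hz default linewidth are package conventions —
no J-coupling evolution or quantum simulation is attempted, which keeps
every recovery property testable at desk scale. An extended singlet table
(PCr, Tau, Ala, GABA, sI) is available. ppm↔Hz conversion places the
transmitter on water at 4.7 ppm.

**Fitting.** `fit_basis()` is a time-domain linear-combination fit in the
spirit of QUEST-style quantitation: nonnegative amplitudes per metabolite
with three shared nuisance parameters (global shift, global extra
broadening, zero-order phase), solved by variable projection — the nuisance
parameters move under Levenberg–Marquardt while amplitudes are profiled out
by nonnegative least squares at every step. Exact basis members are
recovered to 10⁻⁶ relative. Cramér–Rao lower bounds come from the Fisher
information built from the analytic Jacobian of all amplitude-plus-nuisance
parameters at the optimum, with the noise SD estimated from the trailing 10%
of the raw FID (the fit runs on apodized data, where the noise is no longer
white; using the raw-FID sigma keeps the CRLB tied to the acquisition).
CRLBs scale linearly in sigma and the whole fit is scale-equivariant.
`crlb_filter()` applies the standard quality rule — accept when
CRLB/amplitude < 20% (nonpositive amplitudes always rejected) — and
`compute_ratios()` forms tCho/tCr, tCho/NAA, mI/tCr, Lip+Lac/tCr and
Glx/tCr only from accepted constituents. Lactate and lipid are not
separated, matching the protocol's acknowledged overlap at 1.3/0.9 ppm.

**Water referencing.** `fit_water_reference()` fits one damped complex
exponential (complex amplitude in closed form, frequency/damping by LM) to
the unsuppressed acquisition, and `water_scale()` divides metabolite
amplitudes by the relaxation-corrected water amplitude with

$$\text{correction} = \left(1 - e^{-TR/T_{1,\text{water}}}\right) e^{-TE/T_{2,\text{water}}},$$

using the 9.4 T rat-brain values $T_{1,\text{water}} = 2097$ ms,
$T_{2,\text{water}} = 42$ ms. Only arbitrary-unit scaling is provided;
tissue relaxation, water content and partial-volume confounds make absolute
molar units unsupportable here, which is why ratios to tCr are the primary
reporting unit.

## The synthetic cohort

`generate_cohort()` draws per-animal, per-day metric values around the
four-arm group trajectories of `default_cohort_params()` — tissue D rising
to $1.68\times10^{-3}$ mm²/s by day 6 under combination therapy against
$1.25\times10^{-3}$ in controls, falling mI/tCr, Lip+Lac/tCr and tCho/NAA
under treatment, growing tumor volumes, flat Glx/tCr and perfusion
parameters, and day-6-only histology indices. Where the emulated study
reports no number (tCho/tCr at days 0/3 and in the monotherapy arms, the
day-3 tumor volume, perfusion trajectories, the MN58b-arm survival
proportion), the defaults are explicit package conventions chosen once:
day-3 tumor volume interpolates geometrically between days 0 and 6, and the
MN58b arm survives at 64%, between control (58%) and TMZ (85%).

Two modelling choices deserve justification:

* **Lognormal rather than normal draws.** Several metrics have coefficients
  of variation near or above 1 (Lip+Lac/tCr in controls at day 6 is
  7.13 ± 2.49; baseline tumor volume 2.9 ± 3.5 mm³). A normal law would put
  appreciable mass at or below zero, making the per-animal percent-change
  unit ill-defined and its group means explosive. Metrics are therefore
  drawn from a lognormal moment-matched to the stated mean and SD — the
  standard positive-valued model — which preserves the mean/SD contract
  exactly and collapses to the exact mean when SD = 0.
* **Within-animal correlation.** Repeated scans of one animal are
  correlated; draws share an animal-level random effect (rho = 0.7 on the
  log scale) across days. This is what makes per-animal percent change a
  meaningful unit rather than a ratio of independent draws.

Survival uses a constant per-day Bernoulli hazard per arm calibrated to the
study-end survival probability, with censoring at day 6 — the simplest model
consistent with endpoint proportions being the only available information.

What the generator does *not* emulate: spatial heterogeneity within
compartments, EPI distortion or motion, baseline drift and eddy currents in
the spectra, J-modulated multiplet shapes, macromolecule baselines,
inter-scan frequency drift, or dropout other than death. Passing tests
therefore demonstrate correctness of the estimators under the stated noise
models, not robustness to every artifact of in vivo data.

## Cohort statistics

`percent_change()` computes $100\,(x_d - x_0)/x_0$ per animal and metric
(missing or zero baselines are dropped with a warning). `anova_bonferroni()`
runs fixed-effects one-way ANOVA via the textbook sums of squares, with
pairwise pooled-variance t tests (Welch by flag) multiplied by the number of
comparisons performed (configurable to a global count) and capped at 1. The
degenerate all-constant case returns F = 0, p = 1. Kaplan–Meier curves and
two-group log-rank tests delegate to the survival package and are verified
in the tests against hand-computed product-limit and per-event-time
tabulation oracles. `run_study()` orchestrates all of this per metric × day
— on percent changes where a baseline exists, on raw values for
single-day metrics such as the histology indices — plus per-arm KM curves
and pairwise log-rank tests, writing a deterministic CSV bundle.
Printed study percentages of the "X% reduction" form are *not* reproduced as
targets: their computation basis (ratio of group means vs. mean of
per-animal changes) is ambiguous, and the two readings differ materially.

## Numerical and design choices

* Optimizer: Levenberg–Marquardt everywhere a nonlinear fit occurs, max 200
  iterations, cost tolerance 10⁻¹⁰.
* $S_0$ is the arithmetic mean of all b = 0 repeats; b = 0 images enter the
  biexponential and ADC fits but never the high-b stage.
* Multi-direction acquisitions are expected to be trace-combined (geometric
  mean across directions) before entering the fit; the generators emulate
  the trace signal directly.
* Problem sizes in the shipped analyses were chosen for desk-scale
  verification: a 24×24×4 phantom (216 tumor voxels), 1000-repetition
  IVIM Monte-Carlo, 100-repetition MRS chain Monte-Carlo, and the in vivo
  group sizes 16/14/11/11 for the cohort.
* All generators are pure functions of (spec, seed): the global RNG state is
  saved and restored, and two runs of the demonstration pipeline produce
  byte-identical output bundles.
* The FID interchange format serializes doubles at 17 significant digits so
  write→read is bit-exact.

## Known limitations

* $D^*$ is weakly identified by design of the protocol (few low-b points);
  its 20% recovery band is honest, not conservative, and collapses entirely
  when $D^* \lesssim 5\times10^{-3}$ mm²/s overlaps the tissue decay.
* The CRLB is a lower bound computed under a white-noise assumption on the
  raw FID; after apodization the effective noise is colored, so the reported
  CRLB fractions are best interpreted relative to one another.
* The cohort generator reproduces summary statistics, not biology: it
  cannot create the heavy-tailed outliers, dropout patterns or
  scanner-session effects of a real longitudinal study.
* No motion/eddy/distortion correction, no macromolecule baseline, no
  absolute quantification, no mixed-effects longitudinal modelling.
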