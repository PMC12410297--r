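---
title: "Methods: reference-tissue kinetics, SUVR, and diffusion-tensor lesion profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-tissue kinetics, SUVR, and diffusion-tensor lesion profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordquant)
```

This vignette is the package's account of its models, the choices behind
its defaults, and what its simulation-based validation does and does not
establish.

## The kinetic model

A dynamic PET study of the spinal cord cannot rely on arterial sampling, so
regional binding is quantified against a reference region. Under the
one-tissue approximation for both tissues, the simplified reference tissue
model (SRTM) expresses the target curve in terms of the reference curve:

$$C_T(t) = R_1\,C_R(t) + \left(k_2 - R_1 k_{2a}\right)\,
  \big(C_R \otimes e^{-k_{2a} t}\big)(t),$$

with three parameters: relative delivery $R_1 = K_1 / K_1'$ (a blood-flow
proxy), target efflux $k_2$ (1/min), and apparent efflux
$k_{2a} = k_2 / (1 + BP_{ND})$. The distribution volume ratio is
$DVR = 1 + BP_{ND} = k_2 / k_{2a}$.

SRTM2 reduces variance by fixing the reference efflux rate $k_2'$ shared by
all regions of all animals, leaving two free parameters:

$$C_T(t) = R_1 \left[ C_R(t) + (k_2' - k_{2a})\,
  \big(C_R \otimes e^{-k_{2a} t}\big)(t) \right],
  \qquad DVR = \frac{R_1 k_2'}{k_{2a}}.$$

Assumptions worth stating: both regions are adequately described by one
tissue compartment; the reference region is devoid of specific binding (in
the cord scheme it is merely *stable across groups*, which is weaker — DVR
is then a ratio to reference uptake, not an absolute binding measure, and
values below 1 are routine); activities are decay-corrected, so no decay
term appears anywhere.

### Basis-function fitting

For each candidate $k_{2a}$ on a log-spaced grid, the model is linear in
$R_1$ (SRTM2) or in $(R_1, \phi)$ with $\phi = k_2 - R_1 k_{2a}$ (SRTM).
`fit_srtm2()` / `fit_srtm()` solve these sub-fits by weighted normal
equations at the frame level, scan the grid for the minimal weighted
residual sum of squares, and refine the best interior point by
golden-section search (stopping width `1e-6` 1/min). Numerical choices:

* **Fine grid.** TACs are reconstructed on a uniform 0.01-min grid for the
  convolution; residuals are always formed at the frame level, because that
  is how the data exist. The exponential convolution uses the exact
  recursion for piecewise-linear inputs (evaluated via a C-level recursive
  filter), so quadrature error is limited to the piecewise-linear
  representation itself.
* **Framed-to-fine reconstruction.** Mid-time linear interpolation alone
  biases frames where the curve is convex (around the uptake peak). The
  reconstruction therefore applies three fixed-point sweeps that nudge the
  mid-time knots until the reconstruction's frame averages match the framed
  data. With this, noise-free simulate-then-fit recovers DVR to better than
  $10^{-3}$ relative error (the round-trip tests assert this over random
  kinetics).
* **$k_{2a}$ grid bounds**, default `[0.006, 2.0]` 1/min with 100 points.
  The lower bound sits well below any plausible washout; the upper bound is
  set by what the quantification must represent: with $k_2' = 0.1$/min a
  severely injured region with DVR near 0.05 implies
  $k_{2a} = R_1 k_2' / DVR$ above 1/min, and a bound that cannot reach it
  silently censors the worst lesions (their fits end on the boundary,
  are flagged non-converged, and their exclusion biases the injured-group
  mean upward). A boundary optimum or a nonpositive fitted coefficient
  marks `converged = FALSE` — an explicit failure mode preferred over
  constrained optimization.
* **Weights.** Frame-duration weights ($w_i = \Delta t_i$) by default, a
  count-statistics proxy that matches the simulator's noise model
  (variance $\propto C/\Delta t$); uniform weights are selectable since
  the original analysis choice is unknowable.
* **Degenerate targets.** A target exactly proportional to the reference
  makes $k_{2a}$ unidentifiable in SRTM (the residual surface is flat). The
  fit detects a flat surface relative to the weighted data scale
  ($\mathrm{spread} \le 10^{-8} \sum w y^2$) and reports non-convergence
  instead of an arbitrary rate constant.

### Calibrating $k_2'$

`estimate_k2prime()` takes the median of $k_2 / R_1$ over qualifying
first-pass SRTM fits, the standard SRTM2 calibration. The qualifying rule
is *converged fits only* by default (`min_BP = -Inf`): the textbook
$BP_{ND} > 0$ filter presumes a low-uptake reference, and against the
cervical cord or brain stem every cord segment has $DVR < 1$, so that
filter would disqualify all of them. The threshold is exposed for brain
analyses where a $BP_{ND} \ge 0$ rule is meaningful. Calibration uses the
sham group, whose kinetics are unperturbed.

## SUVR

`suvr_window()` computes the duration-weighted mean of target over
reference across the frames lying *fully* inside the window (default
30–60 min; with the default schedule that is exactly six 5-min frames).
Full containment avoids partial-frame weighting ambiguity. The ratio is
invariant to common rescaling, so injected-dose normalization cancels and
raw-activity TACs give the same SUVR as SUV TACs; `to_suv()` exists for
absolute-scale displays.

## The synthetic cohort

`simulate_cohort()` generates data that satisfy the SRTM2 operational
equation *exactly*, so every fit has an analytic truth:

* A tri-exponential plasma input (`feng_input()`, defaults
  $A_1 = 800$ kBq/mL/min, $A_2 = 20$, $A_3 = 10$ kBq/mL,
  $\lambda = (4, 0.5, 0.01)$/min) drives a one-tissue reference region
  ($K_1' \sim N(0.1, 0.01)$ mL/cm³/min between animals,
  $k_2' = 0.1$/min). The plasma model exists only inside the simulator.
* Per region, the true DVR is drawn from the group's Normal(mean, SD)
  truncated above 0.05 (numerical safety), $k_{2a}$ is derived, and the
  target TAC is synthesized by the same convolution kernel the fitter
  uses — but from the *exact* fine-grid reference curve, while the fitter
  sees only framed data.
* Frame noise is additive Gaussian with variance
  $\texttt{noise\_scale} \cdot C / \Delta t$, making short early frames
  noisier, as count statistics do. The default `noise_scale = 0.05` puts
  the late-frame (5-min) SNR near 20–30 at the default activity scale — a
  clean ROI-level rat study; it was chosen once as realistic, not adjusted
  to test outcomes.
* The default frame schedule is 6×0.5, 3×1, 2×2, 10×5 min (60 min total),
  a standard one-hour small-animal framing.

The shipped day-1 and day-9–11 specs encode the study conditions of a T7
contusion experiment: 7 sham vs 9 SCI animals; lesion-segment (SC3) DVR
0.72 ± 0.066 vs 0.28 ± 0.098 on day 1 and 0.66 ± 0.032 vs 0.31 ± 0.052 on
days 9–11; lower-thoracic SC4 0.77 ± 0.043 vs 0.70 ± 0.022 on days 9–11
with no day-1 difference; SC2/SC5 without group differences (0.80/0.85,
SD 0.05 — plausible fill-ins where no group values are reported); a
brain-stem region at 2.2 ± 0.15 relative to SC1 (the ratio implied by the
reported SUVR pairs) so reference switching is exercised; and a day-1
lesion delivery deficit ($R_1 = 0.7$) that recovers by days 9–11
(reported only qualitatively, so the value is a fixture choice).

With n = 7/9 and those SDs, the *truth* group-mean percent reduction
itself has a sampling SD near 5 percentage points; seed-to-seed variation
of the simulated group difference is a property of the study size, not of
the estimator.

**What the generator does not emulate:** scanner physics (attenuation,
scatter, randoms), reconstruction artifacts, motion, partial-volume
effects, plasma metabolites, or violations of the one-tissue assumption.
Passing round-trip tests therefore validates the *estimator* against its
own model class and noise; it does not certify accuracy on real scans,
where model mismatch dominates.

## Diffusion tensor module

`simulate_dwi()` produces $S = S_0 e^{-b\,g^\top D g}$ per voxel/volume
and applies Rician noise (magnitude of a complex-Gaussian perturbation)
when $\sigma > 0$; tensors must be positive semi-definite (checked, with
the offending voxel named). The default scheme is one $b=0$ plus 30
directions at $b = 1000$ s/mm², from an electrostatic-repulsion table
shipped as a text fixture; acquisition geometry is a fixture choice, not a
reproduction of any protocol.

`fit_tensor()` is unweighted log-linear OLS — deterministic, exactly
invertible on noise-free data (the tests assert recovery to $10^{-9}$),
and solved with a single QR for all voxels. Nonpositive signals invalidate
a voxel rather than aborting; multiple $b=0$ volumes are averaged before
fitting. `tensor_metrics()` sorts eigenvalues, clamps negatives to zero
(flagging the voxel) so FA stays in $[0,1]$, defines FA of the zero tensor
as 0, and reports ADC as identical to MD (trace/3) — the two names label
the same quantity in the cord and brain analyses.

The lesion epicenter is the argmin of the moving-average-smoothed
(halfwidth 2 slices, configurable) mean-FA profile along the cord
(`fa_axial_profile()` + `locate_epicenter()`). Raw single-slice minima are
noise-dominated, hence the smoothing; ties resolve to the middle of the
tied run, and an all-flat profile returns the midpoint with a warning.
The cord phantom blends a prolate tensor
($\lambda = (1.7, 0.3, 0.3)\times 10^{-3}$ mm²/s, principal axis along
the cord) toward an isotropic tensor of equal MD with a Gaussian weight
(depth 0.6, width 3 slices) centered on the lesion slice — an FA dip at
constant MD, the signature the localizer must detect.

## Statistics

Group comparisons use the unpaired pooled-variance Student t test
(Welch selectable), one-way ANOVA for multi-group comparisons, and
integer percent change with half-away-from-zero rounding — the rule that
reproduces the reported regional percent differences from their printed
group means. P values are deliberately *uncorrected* for multiple
comparisons, mirroring the source analysis; the comparison table carries
an explicit `corrected = FALSE` column. Zero-variance degenerate inputs
return contractual limits ($p = 1$ for identical constant groups,
$p \to 0$ for shifted constant groups) instead of erroring, so edge-case
simulated cohorts do not crash pipelines. SUVR–DVR agreement is ordinary
least squares with $R^2 = 1 - RSS/TSS$.

## Orchestration

`run_pipeline()` executes simulate (or ingest) → fit → SUVR → compare →
agreement from a single config list or JSON file, deterministically given
the seed; per-region fit failures are logged and excluded, not fatal.
Output tables are stamped with a hash of the config, and reruns are
byte-identical. The package deliberately exposes this as R functions
rather than a shell executable: its users compose analyses in R, and the
per-module functions are the interface.

## Problem sizes used in validation

The test and acceptance runs use: 50 random kinetic parameter sets for the
SRTM2 round-trip; the full 7-vs-9 cohort (6 regions, 21 frames) for the
end-to-end checks; 50–1000 random PSD tensors for the DTI invariants; and
20 noise realizations of the 7×7×80-voxel cord phantom at
$\sigma = S_0/20$ for epicenter localization. These sizes give stable
statistics while keeping a full run in tens of seconds.

## Known limitations

* ROI-level fitting only; no voxelwise parametric images, and no graphical
  (Logan-type) methods.
* The reference-region assumption is stability, not absence of binding;
  DVR values are relative to reference uptake.
* No partial-volume correction — in a structure as small as the rat cord
  this is the dominant unmodeled effect.
* The tensor fit is single-shell Gaussian DTI: no kurtosis, no crossing
  fibers, no eddy/motion correction, no tractography.
* Degenerate-branch p values (0 or 1) are limits, not finite-sample
  probabilities; they exist to keep automated pipelines well-defined.
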