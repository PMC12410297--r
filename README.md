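# cordquant

Reference-tissue PET kinetics and diffusion-tensor quantification for
spinal cord injury (SCI) studies in small animals.

## The problem

After a thoracic contusion injury, synapse loss at and around the lesion can
be imaged in vivo with a synaptic-density PET tracer (an SV2A ligand) and
confirmed ex vivo with diffusion MRI. Quantifying such a study needs four
pieces that this package provides as composable, tested functions:

1. **Reference-tissue kinetic modeling.** Without arterial sampling, regional
   binding is estimated against a reference region. The simplified reference
   tissue model (SRTM) describes a target time–activity curve (TAC) as

   `C_T(t) = R1 C_R(t) + (k2 − R1 k2a) · (C_R ⊗ e^(−k2a t))`

   with relative delivery `R1 = K1/K1'`, target efflux `k2`, and apparent
   efflux `k2a = k2 / (1 + BP_ND)`. SRTM2 stabilizes the fit by fixing the
   reference efflux rate `k2'` (calibrated as the median `k2/R1` over
   first-pass SRTM fits), leaving the operational equation

   `C_T(t) = R1 [C_R(t) + (k2' − k2a) · (C_R ⊗ e^(−k2a t))]`

   which is linear in `R1` for each candidate `k2a`. `fit_srtm2()` solves it
   by basis functions over a log-spaced `k2a` grid with golden-section
   refinement, reporting the distribution volume ratio
   `DVR = R1 k2' / k2a = BP_ND + 1`. DVR may be below 1: cord segments
   quantified against the high-uptake cervical cord (SC1) typically are.

2. **Windowed SUVR.** `suvr_window()` computes the duration-weighted mean
   uptake ratio over frames fully inside a late window (default 30–60 min),
   the static surrogate for DVR, against a switchable reference region
   (SC1, brain stem, whole brain).

3. **Diffusion tensor metrics and epicenter localization.** `fit_tensor()`
   fits `S = S0 e^(−b gᵀ D g)` by log-linear least squares; `tensor_metrics()`
   derives FA, MD/ADC, axial (λ‖) and radial (λ⊥) diffusivity;
   `fa_axial_profile()` + `locate_epicenter()` find the lesion epicenter as
   the minimum of the smoothed mean-FA profile along the cord.

4. **Group statistics.** Unpaired Student/Welch t tests, one-way ANOVA,
   integer percent change between group means (half-away-from-zero
   rounding), SUVR–DVR agreement (OLS `R²`), and per-region comparison
   tables with deliberately uncorrected p values.

A first-class synthetic-data module (`simulate_cohort()`, `simulate_dwi()`,
`cord_phantom_tensors()`) generates cohorts whose TACs satisfy the SRTM2
equation exactly — so fits have analytic ground truth — and Rician-noise
diffusion phantoms with a known lesion position. The shipped sham-vs-SCI
cohort encodes the study conditions of a T7 contusion experiment (7 sham vs
9 SCI; lesion-segment true DVR 0.72 ± 0.066 sham vs 0.28 ± 0.098 SCI on
day 1).

## Worked example

```r
library(cordquant)

# one lesion-like region: R1 = 0.7, k2a = 0.25/min, k2' = 0.1/min -> DVR = 0.28
ref    <- simulate_reference_tac()
lesion <- simulate_target_tac_srtm(ref, R1 = 0.7, k2a = 0.25, k2prime = 0.1,
                                   region = "SC3")
fit_srtm2(lesion, ref, k2prime = 0.1)
#> SRTM2 fit [SC3]: R1 = 0.7001, k2a = 0.25004 /min, DVR = 0.2800
#>   (BP_ND = -0.7200), rss = 0.000108

# full simulated study: simulate -> fit -> compare
report <- run_pipeline(list(cohort = "day1", seed = 1))
report
#> cordquant pipeline report (config 39e926e0)
#>   reference region: SC1; k2prime = 0.10099 /min
#>   SUVR-DVR agreement R^2 = 0.999 (n = 80)
#>   DVR comparison table:
#>  region mean_sham mean_scis          t            p percent_change
#>     SC2 0.7848427 0.8146097 -1.2434534 2.341211e-01             -4
#>     SC3 0.7264232 0.3106968  7.7000382 2.130602e-06             57
#>     SC4 0.7454958 0.7587801 -0.7162995 4.855843e-01             -2
#>     SC5 0.8672097 0.8454544  0.6808540 5.070693e-01              3
#>     BS  2.1247767 2.2352411 -1.8014324 9.320496e-02             -5
```

The noise-free fit recovers the generator truth (DVR 0.2800) to four
decimals. In the cohort run, only the lesion segment SC3 separates the
groups (57% lower DVR at this seed; the generating truth is a 61% mean
difference with between-animal SD, so seed-to-seed group means vary by a
few points), the auto-calibrated `k2'` lands on the generator's 0.1/min,
and the windowed SUVR tracks DVR with `R² = 0.999`.

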