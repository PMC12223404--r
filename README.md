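# memriq

Quantitative analysis of manganese-enhanced cardiac MRI (MEMRI) for acute
myocardial ischemia–reperfusion experiments, with a fully ground-truthed
digital left-ventricle phantom for validation.

Mn²⁺ enters viable, perfused myocytes through calcium channels and
shortens T1, so during a coronary occlusion the perfused myocardium
brightens on T1-weighted images while the ischemic territory does not.
`memriq` turns continuously acquired dynamic series into ischemic-burden
metrics, and implements the companion measurements such studies report:

- **Slope-criterion perfusion deficit** — per-pixel uptake slope over the
  occlusion window, `slope = (SI(t_end) − SI(t_start)) / (t_end − t_start)`
  (or per-voxel OLS), with the deficit defined as the percentage of LV
  myocardium with a nonpositive slope.
- **Septal-reference thresholding** — `mean + k·SD` from a remote septal
  ROI (k = 2 by default): voxels above the threshold give the late
  gadolinium enhancement (LGE) area at risk; voxels below `mean − k·SD`
  give the MEMRI hypo-enhancement deficit at end-occlusion.
- **Variable-flip-angle T1 mapping** — per-voxel fits of the spoiled
  gradient-echo steady state
  `S = M0·sin α·(1 − E1)/(1 − E1·cos α)`, `E1 = exp(−TR/T1)`,
  by linearisation and by Levenberg–Marquardt refinement, plus
  log-polynomial multiplicative bias-field correction.
- **Cine volumetrics and wall mechanics** — EDV, ESV,
  `EF = 100·(EDV − ESV)/EDV` from per-frame label maps; segmental wall
  thickness by radial ray casting and fractional wall thickening
  `fWT = 100·(WT_ES − WT_ED)/WT_ED`.
- **Headline statistics** — Welch two-sample t-test, Spearman rank
  correlation with exact permutation p-values for small cohorts, and
  simple linear regression with intercept confidence intervals.
- **Synthetic phantom** — a short-axis LV annulus on a 120 × 110 × 10 grid
  (28 × 25 × 8 mm³ FOV) with saturating wash-in kinetics, an angular
  ischemic sector of known voxel mask, VFA stacks, LGE volumes with a scar
  sub-sector, 20-frame cine geometry with analytic cavity volumes, bias
  fields, Gaussian noise and optional rigid shifts — so every estimator is
  testable against exact ground truth.

Images and label maps travel as NIfTI-1 with JSON sidecars (RNifti
underneath); metrics come back as plain data frames.

## Worked example

Simulate one occluded subject (true deficit sector spanning a quarter of
the LV), then recover the deficit, the ROI dynamics, and cardiac function:

```r
library(memriq)

spec <- phantom_spec(ischemic_sector = c(-45, 45), seed = 42)
kin  <- uptake_kinetics()      # 11 frames / 66 min, release at 30 min
mem  <- simulate_memri_dynamics(spec, kin)

win  <- split_windows(mem$series, t_occlusion = 30)
smap <- pixel_slope_map(win$ischemia, mem$labels, mode = "endpoint")
deficit_from_slopes(smap, mem$labels)
#> <deficit_result> slope method: 25.22 %LV (580 / 2300 voxels)
mem$truth$deficit_fraction_true
#> [1] 25.21739

fit_window_slope(extract_roi_timecourse(mem$series, mem$labels, "lateral"),
                 "ischemia")[c("slope", "p_nonzero_slope")]
#> lateral ROI: slope -0.501 a.u./min, p = 3.81e-06
fit_window_slope(extract_roi_timecourse(mem$series, mem$labels, "septal"),
                 "ischemia")[c("slope", "p_nonzero_slope")]
#> septal ROI:  slope  2.685 a.u./min, p = 0.00494

cine <- simulate_cine(spec, 20)
ejection_fraction(sapply(cine$frames, cavity_volume))
#> <volumetrics> EDV 58.1 uL (frame 1), ESV 15.7 uL (frame 10), EF 72.99%
```

The deficit estimate equals the phantom's true ischemic fraction to the
voxel; the occluded lateral wall shows a flat-to-negative uptake slope
while the septum brightens significantly; and the global EF (cine here
simulated without regional impairment) lands at the healthy value implied
by the annulus geometry. `run_synthetic_cohort()` repeats this per subject
across IRI / sham / naive groups and returns a tidy metrics table with
ground truth and a seed manifest.

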