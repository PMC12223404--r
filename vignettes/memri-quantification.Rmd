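---
title: "Quantifying acute myocardial ischemic burden with memriq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying acute myocardial ischemic burden with memriq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memriq)
```

## The measurement problem

Manganese-enhanced MRI (MEMRI) exploits the fact that Mn²⁺ enters viable,
perfused myocytes through voltage-gated calcium channels, shortening T1 and
brightening perfused myocardium on T1-weighted images. When a coronary
artery is occluded, the downstream territory receives no tracer: its signal
stays flat or declines while remote myocardium brightens steadily. Imaging
continuously through occlusion and reperfusion therefore turns the *rate of
signal change* into a perfusion marker. `memriq` implements the full
quantitative chain for such experiments in the mouse: per-pixel uptake-slope
mapping and the nonpositive-slope deficit metric, septal-reference
mean + k·SD thresholding (shared by late-gadolinium-enhancement area-at-risk
and MEMRI hypo-enhancement analysis), variable-flip-angle T1 mapping,
cine volumetrics and segmental wall thickening, and the group statistics
used for the headline comparisons — all validated against a digital
left-ventricle phantom with exact ground truth.

## The dynamic model and the deficit metrics

A dynamic acquisition spans 66 min in 11 frames (timestamps are the
midpoints of 11 equal 6-min intervals; the per-frame acquisition duration
is not otherwise resolved, so midpoints are the natural convention), with
occlusion released at 30 min. Analysis splits the series at that point
rather than motion-correcting, because the only appreciable motion is a
small rigid repositioning when the balloon inflates or deflates.

For every myocardial voxel the **slope criterion** computes, over the
ischemia window,

$$\text{slope} = \frac{SI(t_\text{end}) - SI(t_\text{start})}{t_\text{end} - t_\text{start}},$$

the two-point endpoint form being the defining estimator; a per-voxel
ordinary-least-squares alternative over all window frames (`mode = "ols"`)
is provided for noise robustness and coincides with the endpoint form on
exactly linear trajectories. The **perfusion deficit** is the percentage of
LV myocardium voxels with slope ≤ 0 — "nonpositive" is taken literally, so
an exactly flat voxel counts as deficit. The %LV denominator is myocardium
voxels only (cavity excluded), matching how histological infarct fractions
are expressed; on this phantom's uniform slice thickness, pixel counting
and volume weighting are identical.

The **threshold criterion** mirrors clinical late-enhancement analysis: a
reference ROI in the septum (remote, fully perfused territory) supplies a
sample mean and SD, and the threshold is mean + k·SD with k = 2 by default.
For LGE the enhanced fraction counts voxels *strictly above* the threshold;
for MEMRI at the end of occlusion the ischemic territory is
*hypo*-enhanced, so the same technique is applied downward: voxels strictly
below mean − k·SD. Ties at the threshold are excluded — deterministic, and
measure-zero under noise. Both fractions are affine-invariant and
non-increasing in k.

## T1 mapping

Native T1 is estimated from spoiled gradient-echo stacks at flip angles
[2, 5, 8, 11, 14]° with TR 11.1 ms, via the standard steady-state closed
form

$$S(\alpha) = M_0 \sin\alpha \,\frac{1 - E_1}{1 - E_1\cos\alpha}, \qquad
E_1 = e^{-TR/T_1}.$$

The linear fit regresses \(S/\sin\alpha\) on \(S/\tan\alpha\), whose slope
is \(E_1\); voxels with slope outside (0, 1) are flagged invalid rather
than clamped so failure stays visible in the map. A per-voxel
Levenberg–Marquardt refinement on the closed form itself never increases
the residual and constrains T1 to [100, 10000] ms — anything outside is
physiologically meaningless at 7 T. B1 (flip-angle) inhomogeneity is out
of scope.

Multiplicative shading is corrected by fitting, per slice, a polynomial of
total degree ≤ 3 (default 2) to log-intensity inside a mask, normalising
the exponentiated field to unit mean over the mask. Two placement caveats
learned from the phantom: the field must be estimated on a volume without
genuine low-order contrast structure (otherwise the polynomial absorbs real
enhancement), so the pipeline estimates the MEMRI field from the
pre-enhancement baseline frame when correction is requested; and because
the LV annulus occupies the flat centre of an FOV-scale shading field, the
correction is off by default in `analyze_subject()` — shading across the
annulus at the default bias amplitude is below half a percent.

## Cardiac function

Cavity volumes use slice summation — cavity voxel count × voxel volume, in
µL — over label maps per cine frame; end-diastole and end-systole are the
frames of maximal and minimal volume (ties broken by the earliest frame),
and EF = 100·(EDV − ESV)/EDV. Wall thickness casts 16 radial rays per
segment from the cavity centroid on a mid-ventricular slice, measuring per
ray the distance between the first and last myocardial crossing under the
half-voxel centre convention; segments are numbered counterclockwise from
the anterior-septal junction (135°), giving septal, inferior, lateral,
anterior with the default 4 segments (6 AHA-style mid-ventricular segments
are available — the segmental convention is not fixed by the source
analyses, so the 4-quadrant form matching the ROI scheme is the default).
Fractional wall thickening is 100·(WT_ES − WT_ED)/WT_ED per segment.

## The phantom: what it emulates, and what it does not

The generator builds a short-axis annulus (cavity inside `r_endo`,
myocardium to `r_epi`) on the acquisition grid of the emulated study —
matrix 120 × 110 × 10 over a 28 × 25 × 8 mm³ field of view. Defaults,
chosen once as typical for a healthy adult mouse heart and for the group
contrasts of a 30-min occlusion experiment:

| parameter | default | rationale |
|---|---|---|
| `r_endo_ed`, `r_epi_ed` | 1.5, 2.5 mm | EDV ≈ 57 µL, 1 mm diastolic wall |
| `r_endo_es`, `r_epi_es` | 0.8, 2.154 mm | EF ≈ 72%, near-conserved wall area |
| `s0`, `u_max`, `tau_up` | 100 a.u., 1, 15 min | saturating wash-in that roughly doubles signal over the hour |
| `d_rate` | 0.005 /min | mild ischemic decline (−15% over 30 min), frozen after release |
| `noise_sigma` | 2.5 | SNR 40 against baseline |
| `bias_amplitude` | 0.1 | ±10% FOV-scale shading, `1 + A\,\hat x\hat y` |
| `impairment_severity` | 0.6 | regional hypokinesia giving EF in the low 60s at a ~25 %LV deficit |

Perfused tissue follows a mono-exponential saturating wash-in and ischemic
tissue a linear non-increase — the simplest forms consistent with observed
ROI dynamics, since no kinetic model is implied by the data. The ischemic
territory is an angular sector of the lateral wall (centred on 0°); its
width directly encodes the true deficit fraction
(width = 3.6 × %LV over all slices), and the truth manifest stores the
exact voxel mask. IRI-group subjects receive an LGE-enhanced sector that
strictly contains a central scar sub-sector, reproducing the structural
relationship that makes area-at-risk overestimate final infarct size;
sham subjects get a small enhanced rim and no deficit.

One numerical choice deserves note: the annulus is centred on the voxel
centre nearest the grid centre. On even-sized grids the exact grid centre
is a voxel *corner*, and the four-fold lattice symmetry there makes
rasterisation of a small disc (the end-systolic cavity is only ~3.5 voxels
in radius) systematically undercount by double-digit percentages; centring
on a voxel centre restores ordinary discretisation behaviour.

Deliberate simplifications: Gaussian rather than Rician noise (at the
simulated SNR the magnitude distribution is effectively Gaussian, and
Gaussian keeps estimator-bias analysis clean), whole-voxel rigid shifts
(no interpolation ambiguity), no Bloch simulation, gating artefacts,
realistic anatomy, papillary muscles, or partial-volume myocardium. Passing
recovery tests therefore demonstrates estimator correctness under the
stated model — not robustness to the segmentation error, through-plane
motion and B1 inhomogeneity of real acquisitions.

## Statistics

Group contrasts use the two-tailed Welch unequal-variance t-test, with
explicit conventions for degenerate zero-variance inputs (identical
constants: p = 1; differing constants: p = 0, flagged). Agreement between
early imaging metrics uses Spearman rank correlation with midranks for
ties; its p-value is exact — full enumeration of all n! permutations with
the tie-adjusted statistic — for n ≤ 8 (the relevant cohort sizes), with
the usual t-approximation beyond. Simple linear regression reports the
intercept ("offset" between two %LV metrics) with a 95% t-interval. No
multiple-testing adjustment is applied across the headline pairwise
comparisons, matching per-comparison reporting; omnibus ANOVA-family
testing is out of scope.

## Orchestration and problem sizes

`generate_subject()`, `analyze_subject()`, `run_subject()` (on a written
NIfTI directory) and `run_synthetic_cohort()` compose the modules into
per-subject records and a cohort metrics table with a seed manifest;
identical manifests reproduce identical tables. These exported functions,
together with `scripts/acceptance.R`, are the package's operational
surface; no separate shell tool is shipped since users of an R analysis
package drive it from R.

The validation suite runs recovery checks at the full acquisition matrix
for the single-subject criteria, and uses a half-resolution grid
(60 × 56 × 4) for the 100-cohort structural-overestimation study and for
unit tests — the slope, threshold and regression properties being
resolution-free, these sizes were chosen as the smallest that leave the
voxel quantum well below the tolerances being verified.

## Known limitations

Perfusion, not viability: with tracer given at occlusion onset, a
nonpositive slope marks territory the tracer never reached — the analysis
deliberately makes no viability claim. The phantom's sector geometry makes
deficit fractions exactly representable, so recovery "to the voxel
quantum" is a statement about the estimators, not about contouring
accuracy on real hearts. The wall-thickness estimator assumes an annulus
topology per slice and refuses slices where more than a quarter of rays
miss myocardium. T1 fitting assumes ideal spoiling and the nominal flip
angle; transmit-field errors bias T1 multiplicatively and are not
modelled.
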