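---
title: "Methods: hypoxia dynamics and delta-radiomics from longitudinal FMISO-PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hypoxia dynamics and delta-radiomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypoxrad)
```

# The problem

Tumor hypoxia confers radiation resistance. The PET tracer
¹⁸F-fluoromisonidazole (FMISO) accumulates in viable hypoxic cells, so a
series of FMISO-PET scans acquired before and during chemo-radiotherapy
shows whether the hypoxic part of a head-and-neck tumor shrinks, persists,
or relocates. `hypoxrad` turns three co-registered SUV-valued scans per
patient (W0 before treatment, W2 and W5 during treatment) plus a
clinician-drawn boost volume into (i) per-patient hypoxia-dynamics labels,
(ii) a 130-dimensional delta-radiomics profile, and (iii) cohort-level
outcome statistics.

The package assumes SUV normalization and rigid co-registration happened
upstream; it verifies grid agreement (shape exact, spacing/origin within
10⁻³ mm) and refuses misaligned inputs rather than resampling them.

# Segmentation model

The hypoxic sub-volume (HSV) is a threshold set: a boost voxel is hypoxic
when its SUV reaches `tbr` (default 1.4) times the mean SUV of a
background region of normoxic tissue. Choices worth making explicit:

* **Background statistic.** The background region is a user-supplied ROI
  mask; its summary is the arithmetic mean by default (`estimate_background`
  exposes the median as an alternative). The delineation of that ROI is a
  site-specific protocol step, so the package treats it as an input;
  `auto_background_roi()` offers a corner-box construction for synthetic
  work only.
* **Inclusive threshold.** A voxel exactly at `tbr × BG` is included. This
  makes the rule testable bit-exactly at the boundary; the measure-zero
  convention cannot change any volume in continuous data.
* **No post-processing by default.** No hole filling, no smoothing, no
  minimum component size; an optional 26-connected minimum-component
  filter exists behind `min_component_voxels` but is off, because the
  segmentation rule is defined purely by the threshold.
* An empty HSV is a legitimate result (patients without hypoxic volume),
  reported as such, never an error.

# Size and geography of hypoxia change

With the baseline HSV as reference and a later scan's HSV as comparison
(both W0→W2 and W0→W5 use W0 as reference), the relative volume
difference ΔV = 100·(V_new − V_ref)/V_ref feeds a three-band classifier:
increasing hypoxia at ΔV ≥ 15 %, stable within ±15 %, decreasing at
ΔV ≤ −15 %. The printed bands leave ΔV = −15 exactly unassigned; we close
the partition by assigning it to DH, mirroring the inclusive IH boundary.
The 15 % band is a robustness margin against segmentation and
registration noise, not a biological constant.

The classification parameter (CP) quantifies geographic change with the
overlap statistic matched to the size class — DICE for stable, sensitivity
for increasing, PPV for decreasing hypoxia. The point of the branch
structure: whenever the follow-up contour covers the reference in the
branch's sense (superset under growth, subset under shrinkage, equality
under stability), CP equals 1 regardless of the size change, so size and
location dynamics are decoupled. Degenerate cases are explicit labels:
an empty follow-up HSV is `resolved` (CP undefined), an empty baseline is
`absent`.

For survival comparison, patients are dichotomized on CP. The cut-point
is a genuinely open design choice; the default is the cohort median with
ties assigned to the high (static) group, and a fixed threshold is
available (`cp_rule = "threshold"`). Resolved-hypoxia patients have no CP
and are excluded by default; `resolved_as_high = TRUE` maps them to the
static group under the reading "hypoxia gone".

# Radiomics

All features are computed inside the **baseline** HSV; the W0 contour is
transferred voxel-for-voxel to the co-registered W2/W5 scans
(`transfer_contour`), so longitudinal feature changes reflect intensity
dynamics, not re-segmentation.

The 130-feature list is frozen in `radiomics_feature_names()`:
12 first-order statistics, 4 histogram features, 6 shape features, and 36
texture features (9 GLCM, 11 GLRLM, 11 GLSZM, 5 NGTDM) under each of
three variants — plain fixed-bin discretization, wavelet band-pass
filtering, and equal-probability quantization. The analysis-critical
features are `glszm_lgze` (low gray-level zone emphasis, which rises with
the abundance of low-uptake zones and therefore with tracer-distribution
heterogeneity) and `glcm_correlation`.

Numerical conventions, all of which matter for bit-exact reproduction:

* **Discretization.** Fixed bin width W = 0.01 SUV, anchored at the
  in-mask minimum: g = ⌊(s − s_min)/W⌋ + 1. The equal-probability variant
  places boundaries at empirical quantiles (64 levels by default) so each
  level holds a near-equal voxel count, ties permitting.
* **Texture matrices.** GLCM and GLRLM aggregate counts over the 13
  unique distance-1 3D directions into one merged matrix (GLCM
  symmetrized); GLSZM zones and the NGTDM neighborhood use 26-connectivity.
  Matrices are restricted to in-mask voxels; out-of-mask voxels break
  runs and zones.
* **Wavelet band-pass.** One-level 3D discrete wavelet transform
  (Coiflet-1 by default), periodized on an edge-replicated even-sized
  grid, reconstructed with the six mixed (band-pass) sub-bands weighted
  1 and the two pure sub-bands (LLL, HHH) weighted 2 — a 1:2
  band-pass-to-other ratio — then normalized so a constant volume is
  unchanged. The transform is implemented in the package (dense
  orthogonal analysis matrices per axis); tests assert perfect
  reconstruction under unit weights and DC invariance rather than
  comparing against an external library.
* **Degenerate regions.** Features undefined on a single occupied gray
  level (correlation-type, NGTDM contrast, ...) are `NA`, never 0: a
  fabricated 0 would propagate into Δ_RF as a spurious signal.
* **Shape surface.** The exposed-face surface area is divided by 3/2, the
  expected staircase inflation for an isotropically oriented smooth
  boundary, so a voxelized sphere approaches sphericity 1. The correction
  over-compensates for blocky shapes (a cube's "sphericity" exceeds 1);
  sphericity is reported as a descriptor, not clipped.

Delta-radiomics are relative deviations Δ_RF = (RF_Wk − RF_W0)/|RF_W0|,
`NA` when the baseline value is 0 or missing.

# Outcome statistics

Survival endpoints (PFS, OS; months from treatment start) use
Kaplan–Meier estimates and the two-group log-rank test; hazard ratios
come from Cox partial likelihood with Wald 95 % CIs (Breslow tie
handling, which keeps the score equation exactly invariant under dataset
replication — a property the tests exploit). Binary endpoints (local
recurrence, distant metastasis) use the Mann–Whitney U test for p-values
(exact for ≤ 20 untied observations) and a single-feature logistic model
for discrimination.

"Imbalance-adjusted bootstrap" is implemented as a class-stratified
bootstrap with equal per-class resampling weight: each of B replicates
(default 1000) draws half the cohort from each outcome class with
replacement, refits the logistic model, and evaluates AUC and the
specificity at the operating point where sensitivity and specificity are
closest; reported values are bootstrap means, coefficients likewise. The
plain bootstrap is available (`stratified = FALSE`). Because a
single-feature logistic score is monotone in the feature, the AUC is
rank-based and essentially free of overfitting optimism; the balanced
resampling keeps minority-class patients from being under-represented.

Multiple testing is controlled per endpoint × time-point across the
130-feature family with Benjamini–Hochberg. Redundancy among
well-predicting features is removed greedily: features are visited by
ascending p-value and kept only if not Spearman-correlated beyond
|ρ| > 0.8 with an already-kept feature. Finally, a feature's predictive
value counts only when BH-adjusted significance holds at W2 **and** W5
for the same endpoint (`two_timepoint_confirmation`); continuous features
enter survival tests through a cohort-median dichotomization, like CP.

# The synthetic cohort generator

`generate_cohort()` emulates the data structure the analysis assumes, at
desk scale:

* Gaussian background at mean 1.0 g/mL, additive noise SD 0.05 g/mL
  (no point-spread blurring — threshold-boundary behaviour is tested on
  noise-free phantoms instead), 64³ grid at 2 mm isotropic by default.
* A spherical boost volume containing a hypoxic core tiled with cubic
  intensity zones at two SUV levels (1.7 and 2.4 × background, both above
  the 1.4 threshold); the low-zone probability is the heterogeneity
  parameter, and its on-treatment increase raises LGZE.
* Per-patient dynamics classes (`static_IH/SH/DH`, `dynamic`, `resolved`)
  with the default mixture placing 64 % of patients in the
  decreasing-hypoxia band at W2, reflecting the typical predominance of
  shrinking hypoxia under chemo-radiotherapy. Follow-up cores realize the
  drawn ΔV **exactly in voxel counts** (the n closest in-boost voxels to
  the, possibly drifted, core center) so that voxelization cannot blur
  the planted class; dynamic patients' cores additionally drift 12 mm.
* Outcomes: exponential PFS (median 20 months for static patients) with
  a hazard ratio of 3 for geographically dynamic patients; 20 %
  of patients censored at a uniform fraction of their event time; local
  recurrence follows a logistic link, calibrated by numerical integration
  (`calibrate_logistic_link`) to a chosen population AUC (default 0.8)
  and prevalence (0.48), on a latent severity score that also drives the
  patient's heterogeneity increase — the planted ΔLGZE is monotone in the
  score, so rank-based discrimination transfers to the measured feature.

What the generator does **not** emulate: PET physics (scatter, randoms,
reconstruction artifacts), partial-volume effects, inter-scanner
variability, irregular lesion shapes, and registration error. Passing
tests therefore demonstrate the correctness and calibration of the
analysis pipeline, not clinical performance on real FMISO data.

`simulate_feature_cohort()` is the reduced form for statistical
calibration studies: it draws delta-feature tables and outcomes directly
(null or single-feature logistic link), skipping the imaging stages whose
correctness is established separately.

# Calibration study sizes

The test suite checks, on synthetic cohorts: recovery of planted size
classes and cores (DICE ≥ 0.9); ≥ 80 % log-rank power on CP groups over
200 replicate image-level cohorts (n = 40, hazard ratio 3, 20 %
censoring, balanced dynamic/static arms on 32³ grids with 6–8 mm cores);
a near-zero confirmed-feature rate on 200 null cohorts; and bootstrap-AUC
bias below 0.05 against a planted AUC of 0.8 at n = 50 over 200
replicates (B = 100 per replicate). The texture engine is verified
against brute-force enumeration oracles on ≤ 5³ grids, feature by
feature, to 10⁻⁶ relative error.

# Known limitations

* The Appendix-level specification of the clinical background-ROI
  protocol is not reproduced; the ROI is an input.
* The exact composition of the original 130-feature catalogue is
  reconstructed from the feature families named in the methods; the
  frozen list here is internally complete and stable but not certified
  feature-by-feature against the original extraction code.
* GLCM/GLRLM direction handling is the merged (summed) strategy only;
  per-direction feature averaging is not implemented.
* The wavelet variant applies fixed-bin discretization to filtered
  values whose scale differs from SUV; the shared bin width of 0.01 is a
  convention, and filtered-variant features should only be compared
  within that convention.
* `run_study()` re-runs stages deterministically from the seed rather
  than caching stage outputs by content hash.
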