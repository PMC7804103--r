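---
title: "Quantifying residual enhancing tumor on early post-operative MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying residual enhancing tumor on early post-operative MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resectquant)
```

## The problem and the model

Post-surgical MRI of glioblastoma shows a rim of contrast enhancement
around the resection cavity. Part of that rim is residual tumor; part of
it, especially in the first day after surgery, is benign reactive
enhancement. `resectquant` quantifies the rim objectively — its thickness,
volume, perfusion characteristics and texture — and relates those
quantities to survival, overall and as a function of the delay between
surgery and the scan.

The central statistic is the **enhancement thickness**: the mean (and
maximum) of the 3D Euclidean distance transform computed inside the
segmented enhancing rim. For each foreground voxel the transform is the
distance in millimetres to the nearest background voxel center, computed
exactly (per-axis lower-envelope algorithm) with anisotropic voxel spacing
honoured. Two conventions matter and are fixed here:

* **Boundary convention.** The array boundary counts as background: the
  grid is implicitly padded by one background layer, so a mask touching
  the volume edge still has a finite distance. The brute-force oracle used
  in the tests applies the identical convention.
* **Shell interpretation.** For a closed rim of true thickness *t*, the
  transform's maximum is about *t*/2 — the distance to the nearer of the
  two boundaries. The statistic remains strictly monotone in *t* (the
  tests verify this across 2/4/6/8 mm rims), which is what the prognostic
  models use; absolute rim thickness would be twice the transform value
  for an ideal shell.

Thickness is computed at the native slice resolution (typically 5 mm
slices), not after the 1 mm radiomics resampling; this is configurable.

## Preprocessing choices

* **Bias correction** is an N4-style simplification: the log-intensity in
  the foreground is fitted by a mask-normalized Gaussian kernel regression
  at the control-grid scale (default 30 mm, sigma = half the control-grid
  spacing), mean-centered so the global intensity scale is preserved, and
  removed multiplicatively over `max_iters` iterations. The estimated
  field has no energy above the control-grid scale by construction. This
  is adequate for smooth coil bias; it does not implement N4's histogram
  sharpening and will partially absorb genuine anatomy at very low spatial
  frequencies.
* **Intensity standardization** uses Nyúl landmark mapping with min/max
  plus decile landmarks (the common variant; the landmark set is a
  configuration choice, not inferred from data). The mapping is continuous
  piecewise-linear, monotone, and linearly extrapolated beyond the end
  landmarks with the end-segment slopes.
* **Subtraction order.** The enhancement map is T1wC − T1w(matched):
  enhancement is contrast uptake and must be positive.
* **Registration** maximizes normalized cross-correlation over the
  6-parameter rigid group with a translation-first, then full,
  Nelder-Mead search on Gaussian-smoothed volumes. NCC suffices for
  same-patient T1w/T1wC pairs; cross-modality registration would need
  mutual information and is out of scope.
* **Intensity matching** between sequences is a gain/offset model fitted
  on non-enhancing voxels by moment matching (mask mean and SD equalized),
  so the subtraction map is zero-mean over normal tissue.

## Perfusion parameters

DSC acquisitions without contrast preload leak gadolinium into tissue, so
leakage correction is mandatory, not optional, in the default pipeline.

* **Curve selection** low-pass filters each curve (moving average, width
  3), min–max normalizes it to [−1, 0] (bolus dip at −1), and fits a
  Gaussian dip plus a recovery step by least squares; the curve is kept
  iff the Pearson correlation with the fitted model reaches
  `gaussian_r_min` (default 0.9 — a declared stand-in, the source
  procedure is not published in detail). The recovery-step regressor is
  needed because physiological curves plateau below baseline; a pure
  Gaussian caps the attainable correlation for perfectly clean curves.
* **ΔR2\*** uses TE in seconds; the baseline S₀ is the mean of the
  declared pre-bolus samples (default 10).
* **Boxerman correction** regresses each voxel curve on the non-enhancing
  reference and its running (trapezoidal) integral. Positive K2 means
  T1-dominant leakage: the post-bolus *signal* drifts above the leak-free
  plateau, which is why PSR above 100% is a legal and clinically meaningful
  regime. The synthetic generator injects leakage in exactly this model,
  so the tests can demand exact (≤1%) recovery of K1 and K2.
* **rCBV** integrates the corrected ΔR2\* over the bolus window (detected
  on the reference curve: from the end of the baseline to the post-peak
  10%-of-peak crossing) and normalizes by the contralateral white-matter
  mean, which is therefore 1 by construction. The hot-spot summary is the
  99th percentile with the linear-interpolation convention (R quantile
  type 7): for values 1..100 it is 99.01, and the tests pin this.
* **PSR** uses the last 25% of samples as the post-bolus plateau. Note PSR
  is invariant under any positive affine rescaling of the curve (it is a
  ratio of signal differences).

## Radiomics

94 features in six families (first-order 19, GLCM 24, GLRLM 16, GLSZM 16,
NGTDM 5, GLDM 14), computed after resampling to 1 mm isotropic voxels and
fixed-bin-width discretization with the bin anchored at the mask minimum:
level(v) = floor((v − min)/w) + 1, default w = 10 intensity units. The
phrase "binarization to 10 levels of bin-width" in reproducibility
protocols is ambiguous; fixed bin *width* is the reading recommended by
that literature and is the default, with a fixed-bin-*count* mode behind
`bin_mode = "count"`. Texture matrices use the 13 unique 3D directions at
Chebyshev distance 1, symmetric GLCM, features averaged over directions;
GLSZM zones and GLDM dependencies use 26-connectivity with dependence
tolerance α = 0. Logs are base 2 with a machine-epsilon guard.

Robustness is screened by re-extracting over a perturbation grid (default
spacing {1, 2} mm × bin width {5, 10, 20}; the source protocol's exact
grid is not published) and computing CoV = 100·sd/|mean| per feature;
robust ⇔ CoV < 20%. Features with zero mean across perturbations have no
defined CoV and are flagged separately. Which features pass is
data-dependent; the package asserts the contract (94 entries, counts per
family), not a particular robust subset.

No independent reference extractor is available in this environment, so
oracle agreement is established at the matrix level: brute-force GLCM
pair-counting and run-walking implementations in the test helpers, plus
translation/shift invariance properties.

## Survival layer

* Cox fits use Efron tie handling; hazard ratios are reported per unit of
  covariate with 95% Wald intervals.
* The dichotomized endpoint is 2-year overall survival; patients censored
  before 2 years are excluded from logistic/ROC analyses but retained in
  Cox/KM analyses.
* The train/test split (70/30) stratifies on the dichotomized outcome;
  features are z-scored with training-set statistics only.
* mRMR estimates mutual information on tercile-discretized features; ties
  break lexicographically, making selection deterministic. Stepwise
  selection is bidirectional on AIC; quasi-separation triggers a ridge
  refit with a warning.
* AUC is the Mann–Whitney concordance probability; its CI and the p-value
  against 0.5 use DeLong's placement method. Youden thresholds resolve
  ties to the lowest threshold.
* Subgroup analyses fit one Cox model per scan-delay window; p-values are
  BH-adjusted within each covariate family by default (`adjust_scope =
  "global"` adjusts all rows as one family — the source's adjustment scope
  is ambiguous, so both are implemented). Windows with fewer than 10
  events are flagged unstable. Note that BH is *not* idempotent in the
  strict sense (re-adjusting adjusted p-values can only move them up);
  the tests assert the correct monotone/step-up properties.

## What the synthetic world does and does not establish

The phantom generator produces: a spherical resection cavity with a
closed-shell enhancing rim (voxel-center membership decides partial-volume
voxels), piecewise-constant tissue intensities, a single low-frequency
cosine bias mode, additive Gaussian noise, gamma-variate DSC boluses with
Boxerman-model leakage, and exponential survival with log-linear hazard in
rim thickness and exponential non-informative censoring calibrated to the
target censor fraction. Defaults mirror the stated acquisition world:
1×1×5 mm voxels, 10 pre-bolus baseline samples, TE 40 ms, ~60 dynamics, a
144-patient cohort with scan-delay window frequencies 26/51/42/25ths,
age ≈ N(59, 12²), thickness ≈ N(3, 1.5²) mm truncated at 0.1 mm.

A green test therefore establishes algorithmic correctness (parameter
recovery, oracle equality, contract compliance) — not clinical validity.
The phantoms have no real anatomy, skull, motion, multi-coil noise or
arterial input function variability, and the cohort has no correlated
covariates; cohort-level numbers from real patients (hazard ratios, AUCs,
Youden cut-offs) are not reproducible from synthetic data and are not
claimed.

For the window-restricted end-to-end check, the hazard–thickness link is
attenuated to 5% of its log-coefficient in the <24 h and ≥72 h windows
(multipliers 0.05/1/1/0.05). The value was fixed a priori by a power
calculation — with ~100 patients per window and thickness SD 1.5 mm the
edge-window Wald z is ≈0.5, giving a ≈6% false-flag probability per edge
after BH while the middle windows have power ≈1 — and was not revisited
after running the tests.

## Known limitations

* The NIfTI-1 reader/writer is minimal (single-file, common datatypes,
  qform identity rotation); it is not a general NIfTI library.
* Bias correction absorbs very-low-frequency anatomy; for real data a full
  N4 implementation is preferable.
* Registration is rigid, intra-patient, correlation-based.
* The segmentation threshold has no universal default: it is a required
  configuration value, chosen relative to the expected rim contrast.
* mRMR's MI estimation uses fixed tercile binning; with very small
  training sets the estimates are coarse.
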