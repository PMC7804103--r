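# resectquant

Quantification of residual enhancing tumor on early post-operative MRI of
glioblastoma.

After maximal safe resection of a glioblastoma, the amount of residual
enhancing tumor seen on the early post-operative MRI (EPMR, acquired within
hours to days of surgery) is prognostic — but it is usually judged by eye.
`resectquant` replaces that subjective call with a reproducible pipeline:

1. **Enhancement mapping.** The pre-contrast T1-weighted volume (T1w) is
   bias-corrected, intensity-standardized (Nyúl landmark mapping), rigidly
   registered and linearly intensity-matched to the post-contrast volume
   (T1wC); the voxelwise subtraction T1wC − T1w isolates contrast uptake.
2. **Thickness of the enhancing rim.** The rim is segmented by thresholding
   plus morphology, and its thickness is quantified as the mean and maximum
   of the exact anisotropic 3D Euclidean distance transform
   d(v) = min over background voxels b of ‖x(v) − x(b)‖ (mm), inside the
   mask, plus the mask volume in mL.
3. **DSC perfusion.** Bolus-bearing curves are selected by resemblance to a
   fitted Gaussian dip, converted to ΔR2\*(t) = −(1/TE)·ln(S(t)/S₀),
   leakage-corrected with the Boxerman–Schmainda–Weiskoff linear model
   ΔR2\*(t) ≈ K1·ref(t) − K2·∫ref, and summarized as the white-matter
   normalized 99th-percentile rCBV (rCBV-99) and the maximum percentage of
   signal recovery, PSR = 100·(S_post − S_min)/(S₀ − S_min).
4. **Radiomics.** A 94-feature IBSI-style vector from the enhancement mask
   on T1wC (first-order 19, GLCM 24, GLRLM 16, GLSZM 16, NGTDM 5, GLDM 14)
   after 1 mm isotropic resampling and fixed-bin-width discretization, with
   coefficient-of-variation robustness screening (robust ⇔ CoV < 20%)
   across extraction-parameter perturbations.
5. **Prognostic modelling.** Cox proportional hazards (Efron ties) and
   Kaplan–Meier/log-rank analyses overall and per surgery-to-scan window
   (<24 h, 24–<48 h, 48–<72 h, ≥72 h; Benjamini–Hochberg adjusted),
   2-year dichotomized logistic/ROC models with Youden thresholds,
   stratified 70/30 train/test splitting, z-normalization with training
   statistics, and mRMR + stepwise-AIC feature selection.

Because no patient data ship with the package, a synthetic-data module
generates phantoms and cohorts with known ground truth (rim thickness,
leakage K2, hazard coefficients) so that every stage can be validated by
parameter recovery.

## Worked example

```r
library(resectquant)

# a phantom patient: resection cavity, 4 mm enhancing rim, 5 mm slices
spec <- phantom_spec(rim_thickness_mm = 4, noise_sd = 5,
                     bias_amplitude = 0.1, seed = 42)
ph <- make_phantom_pair(spec)

t1w  <- correct_bias(ph$t1w)$corrected
t1wc <- correct_bias(ph$t1wc)$corrected
fg <- t1wc$values > mean(t1wc$values)
d  <- t1wc$values - t1w$values
nonenh <- fg & d < quantile(d[fg], 0.95)
matched <- match_intensity(t1w, t1wc, nonenh)$matched
mask <- segment_enhancement(subtract(t1wc, matched), threshold = 150)
thickness_stats(mask)
#> <thickness_result> mean 2.07 mm, max 5.00 mm, volume 10.200 mL (2040 voxels)
```

The mean transform value (2.07 mm) is the average distance of a rim voxel
to the mask boundary — for a shell it approaches the half-thickness of the
rim — and is the covariate used in the survival models. On a synthetic
cohort whose hazard doubles per mm of rim thickness:

```r
co <- make_cohort(cohort_spec(n_patients = 144, seed = 42))
cox_fit(co$records, "mean_thickness_mm", "OS")
#>           covariate       hr ci_lower ci_upper            p   n n_events
#> 1 mean_thickness_mm 2.385831 1.992304 2.857088 3.236243e-21 144      109
```

The fitted hazard ratio per mm (2.39, 95% CI 1.99–2.86) recovers the
generating value 2 within its confidence interval at this cohort size.
`subgroup_analysis(co$records, "mean_thickness_mm")` produces the
per-scan-delay-window Cox table with BH-adjusted p-values, and
`run_cohort()` writes it as a markdown report.

## Command line

```sh
resectquant simulate   --spec spec.yaml --out DIR
resectquant preprocess --t1w a.nii.gz --t1wc b.nii.gz --out DIR
resectquant thickness  --mask m.nii.gz          # prints {mean_mm, max_mm, volume_ml}
resectquant perfusion  --dsc d.nii.gz --mask m.nii.gz --wm wm.nii.gz
resectquant radiomics  --image i.nii.gz --mask m.nii.gz
resectquant analyze    --cohort cohort.csv --out report/
resectquant run        --config config.yaml
```

The executable lives at `inst/cli/resectquant` (on the installed package:
`system.file("cli", "resectquant", package = "resectquant")`).

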