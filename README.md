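# ctperfusion

Quantitative analysis of dynamic (4D) CT perfusion of the pancreas, for
imaging researchers who want a kinetic-model-free vascular biomarker of
pancreatic ductal adenocarcinoma (PDAC). Most PDAC is hypovascular, but
10–20% of tumors are isovascular — invisible against normal parenchyma on
conventional CT and associated with longer survival. `ctperfusion` turns a
co-registered perfusion series plus a label map (or per-ROI time–intensity
tables) into per-patient perfusion features, a cross-validated phenotype
prediction, and a survival comparison; a seeded synthetic generator makes
every stage verifiable without patient data.

## The model

A region-of-interest time–intensity curve (mean attenuation in HU vs
acquisition time in s) is described by a **trilinear model** with three
phases — non-enhancement, upslope, washout:

```
y(t) = b                      t ≤ t0        (static line)
y(t) = b + m (t − t0)         t0 < t ≤ tp   (upslope, slope m in HU/s)
y(t) = P + w (t − tp)         t > tp        (washout)
```

The fit is two-step: (1) a cubic smoothing spline over the whole curve
locates the maximum of the analytic derivative; (2) the five timepoints
surrounding that maximum form the upslope phase, everything before is the
non-enhancement phase, everything after the washout phase, and each phase
is fitted by least squares. The start of enhancement `t0` is the
intersection of the static and upslope lines, the peak `tp` the
intersection of the upslope and washout lines, and peak enhancement
`P = m (tp − t0)` is reported above baseline. Three features feed a
ridge-logistic phenotype classifier with stratified 5-fold
cross-validation: tumor slope (HU/s), tumor peak enhancement (HU), and the
pancreas-minus-tumor peak-enhancement difference ΔHU. Survival between
phenotypes is compared with Kaplan–Meier estimates and the log-rank test.

## Worked example

Fit one synthetic curve (true onset 7 s, slope 2.4 HU/s, peak 24 HU,
noise 1 HU) and run the full synthetic cohort end to end:

```r
library(ctperfusion)

g <- generateTIC(onset = 7, slope = 2.4, peakEnhancement = 24,
                 washoutSlope = -0.25, noiseSd = 1, seed = 3)
fitCurve(g$curve)
#> TrilinearFit (non-enhancement / upslope / washout)
#>   baseline level :   39.463 HU
#>   slope          :    2.313 HU/s
#>   onset          :    6.561 s
#>   peak time      :   17.003 s
#>   peak enh.      :   24.151 HU (above baseline)
#>   washout slope  :   -0.247 HU/s
#>   rss            :   15.397
#>   upslope window : indices 5..9
```

The fitted slope (2.31 HU/s), onset (6.6 s) and peak enhancement
(24.2 HU) recover the generating values to within the noise; the window
indices say which samples were treated as the upslope.

```r
res <- runPipeline(validatePipelineConfig(list(seed = 42L)),
                   outputDir = "ctp_out")
res$model
#> PhenotypeModel: 5-fold cross-validated logistic regression
#>   per-fold AUC : 0.946 1.000 0.929 1.000 0.946
#>   mean AUC     : 0.964
#>   pooled AUC   : 0.954
```

This generates the default 92-patient cohort (72 hypovascular + 20
isovascular, noise SD 3 HU), fits both ROIs of every patient, and writes
`features.csv`, `fit_diagnostics.csv`, KM curves and a JSON report to
`ctp_out/`. The feature tests in the report separate the phenotypes
decisively (e.g. tumor slope 2.07 ± 0.61 vs 3.17 ± 1.28 HU/s,
Mann–Whitney p = 1.1e-4), while the survival split at the published group
medians is — as expected at these sample sizes — only marginal
(log-rank χ² = 1.26, p = 0.26 at this seed).

Volumetric inputs work the same way: `readDynamicSeries()` +
`readLabelMap()` + `extractTIC()` reduce a 4D NIfTI series and a label map
to curves, excluding vessel/stent voxels from the tumor ROI before
averaging. A thin command-line front end is installed under
`inst/scripts/ctp.R` (`fit`, `features`, `synth tic|cohort|phantom`,
`run`).

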