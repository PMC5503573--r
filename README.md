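# metabscreen

Marker screening and classification for untargeted urine metabolomics.

## What this package is for

Untargeted LC-MS profiling turns each urine sample into a vector of
intensities over thousands of *spectral ions*, each labelled by retention
time and mass-to-charge, e.g. `(2.56 min: 314.085 m/z)`; a zero intensity
means the ion was not detected in that sample. Given such a feature table
for a case-control cohort (the motivating setting is bladder-cancer
patients against hernia controls), `metabscreen` answers three questions:

1. **Which ions are candidate markers?** A four-stage screening cascade on
   the training split:
   * detection in strictly more than half of the training samples;
   * positive log₁₀ fold change (case mean / control mean, zeros included)
     more than one SD above the mean of a three-parameter Gaussian
     `A·exp(−(x−μ)²/2σ²)` least-squares fitted to the log-fold-change
     histogram — down-regulated ions are never kept;
   * two-sided Wilcoxon rank-sum p < 0.05;
   * ROC AUC = (#{case > control pairs} + ½·ties)/(n₁n₂) ≥ 0.7.
2. **Do the candidates separate the groups?** From-scratch OPLS-DA (NIPALS,
   one predictive + configurable orthogonal components, R²X/R²Y/Q²
   diagnostics with stratified 7-fold CV) and locally linear embedding
   (k-NN reconstruction weights summing to 1, bottom eigenvectors of
   (I−W)ᵀ(I−W)).
3. **How well does a classifier built on them generalise?** A gain-ratio
   (C4.5-style) decision tree with midpoint splits on continuous
   intensities and confidence-based subtree-replacement pruning, evaluated
   by stratified 5-fold cross-validation on the training split and by an
   independent held-out test split, reporting accuracy, sensitivity and
   specificity.

A synthetic cohort generator (`simulate_cohort()`) produces two-group
cohorts with zero-inflated log-normal ion intensities and planted
up-regulated markers, so every stage is testable against ground truth.

## Worked example

```r
library(metabscreen)
cfg <- pipeline_config(
  cohort = cohort_config(n_ions = 2000, marker_fold_range = c(10, 10),
                         seed = 11)
)
run_pipeline(cfg)
```

```
== Marker discovery pipeline report ==
Four-stage marker screening
  ions in: 2000 | detected: 1632 | fold: 308 | rank-sum: 52 | AUC: 6
  log-ratio Gaussian: mean -0.004, sd 0.080
Candidate ions (6):
                      ion #case #control ratio        p  AUC
 (11.66 min: 238.031 m/z)    53       48  8.57 2.75e-16 0.96
  (1.82 min: 282.223 m/z)    52       50  8.37 3.79e-14 0.93
  (6.60 min: 142.940 m/z)    51       46 12.00 3.94e-14 0.93
 (10.49 min: 156.185 m/z)    51       48  8.52 4.17e-14 0.93
  (4.93 min: 737.628 m/z)    51       49  8.95 4.39e-14 0.93
  (0.85 min: 259.727 m/z)    51       45 11.09 9.01e-14 0.92
Planted markers recovered: 6 of 6

5-fold stratified cross-validation (SD convention: sample)
 fold accuracy sensitivity specificity
    1    95.24       90.91         100
    2    90.48       81.82         100
    3    95.24      100.00          90
    4   100.00      100.00         100
    5    95.24      100.00          90
mean: 95.24% +/- 3.37 | 94.55% +/- 8.13 | 96.00% +/- 5.48

Final tree (fitted on the full training split):
Gain-ratio decision tree: 5 node(s), 3 leaf/leaves, 105 training samples
(11.66 min: 238.031 m/z) <= 1924562.3784570841
|   (1.82 min: 282.223 m/z) <= 22380.20311242995
|   |   -> control (50/0)
|   (1.82 min: 282.223 m/z) > 22380.20311242995
|   |   -> case (3/0)
(11.66 min: 238.031 m/z) > 1924562.3784570841
|   -> case (52/0)

Independent test: accuracy 100.00%, sensitivity 100.00%, specificity 100.00% (tp 32, fn 0, tn 15, fp 0)
```

Reading the report: the screening funnel shows how many ions survive each
stage (2000 → 1632 → 308 → 52 → 6); the candidate table lists per-group
detection counts, linear fold change, rank-sum p and AUC, sorted by
ascending p; all six planted tenfold markers were recovered; the CV table
gives per-fold percentages with their mean ± sample SD; the rule listing
shows the final tree's thresholds on raw intensities; and the independent
test reports the confusion counts behind each percentage. The strong
numbers reflect the strong planted effect (tenfold, low dropout) — a null
cohort run collapses to majority-class performance.

The individual stages are available directly: `screen_markers()`,
`fit_gaussian_log_ratios()`, `rank_sum_test()`, `auc()`, `opls()`, `lle()`,
`c45()`, `cross_validate()`, plus tab-delimited readers/writers
(`read_matrix()`, `write_ionstats()`, ...) for interoperability.

See the vignette (`vignettes/marker-screening.Rmd`) for the model
assumptions, parameter choices and limitations.

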