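---
title: "Marker screening and classification for untargeted urine metabolomics"
author: "metabscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker screening and classification for untargeted urine metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabscreen)
```

## The problem

Untargeted LC-MS profiling of urine yields a feature table: for every
subject, an intensity for each of thousands to hundreds of thousands of
*spectral ions*, each identified by a retention time / mass-to-charge pair
and written `"(2.56 min: 314.085 m/z)"`. In a case-control design (here
motivated by bladder-cancer detection against non-cancer surgical
controls), the analytical task is to find the small set of ions whose
intensity separates the groups, to verify that the selected ions carry
multivariate structure, and to quantify how well a classifier built on them
generalises.

`metabscreen` implements that workflow end to end, together with a
synthetic cohort generator that provides ground truth for testing every
stage.

## The screening cascade

Screening operates on the **training split only** and applies four filters
in sequence; each stage only removes ions, so the candidate set at stage
$k$ is always a subset of stage $k-1$.

1. **Detection.** An ion is retained only if it has nonzero intensity in
   strictly more than half of the training samples, pooled over both
   groups. A zero intensity means "not detected"; no separate missing-value
   code exists anywhere in the pipeline. With 105 training samples the
   threshold is therefore 53 detections.

2. **Fold change.** Per ion, the fold change is the ratio of the case-group
   mean intensity to the control-group mean (zeros included; a config
   switch `zero_in_means = FALSE` gives detected-only means for sensitivity
   analysis). The $\log_{10}$ fold changes of all retained ions are
   histogrammed into equal-width bins and a three-parameter Gaussian
   $A\,e^{-(x-\mu)^2/2\sigma^2}$ is least-squares fitted to the
   (bin-centre, count) pairs. An ion survives iff its log ratio is
   **positive** and lies more than one fitted $\sigma$ above the fitted
   $\mu$. Down-regulation is never trusted: a low or zero signal cannot be
   distinguished from a missed detection.

3. **Rank-sum test.** Two-sided Wilcoxon rank-sum p-value below
   $\alpha = 0.05$, with no multiple-testing correction — the cascade is a
   screening device, not an inferential claim, and the subsequent filters
   and the independent test set carry the error control. This is stated
   prominently because it is the design's most debatable choice.

4. **AUC.** The ROC area $\mathrm{AUC} =
   (\#\{x_\text{case} > x_\text{control}\} + \tfrac12\#\text{ties})/(n_1 n_2)$
   must reach 0.7. The AUC is the normalised Mann-Whitney $U$, so stages 3
   and 4 look at the same statistic through two thresholds — the p-value
   scales with $n$, the AUC measures effect size.

Final candidates are reported sorted by ascending p-value.

### Choices the cascade fixes

* "More than half" is read strictly (`> N/2`), pooled over groups; the
  per-group detection counts are reported for the survivors.
* Fold change uses means including zeros. Including zeros makes the ratio
  an estimate of the *detected mass* ratio; excluding them estimates the
  conditional intensity ratio. Both are defensible; the default mirrors the
  single-matrix representation.
* Log base 10. The $\pm 1\sigma$ rule is scale-equivariant, so the base
  only changes the axis of the histogram, not the selected set.
* The Gaussian is fitted to histogram counts (the amplitude parameter is
  only meaningful in count units) with 100 bins by default, by
  Levenberg-Marquardt least squares; a degenerate histogram falls back to
  the sample mean/SD of the log ratios with a warning flag.
* The rank-sum p is exact (null enumeration) when $n_1+n_2 \le 12$ without
  ties, otherwise the normal approximation with tie and continuity
  correction. Two-sided, the conservative default.

## Separation assessment

**OPLS-DA.** `opls()` is a NIPALS implementation for a single two-class
response encoded $y = \pm 1$ (case $= +1$). Orthogonal components —
systematic X-variation uncorrelated with $y$ — are extracted and deflated
first, then one predictive component is fitted. Diagnostics are
$R^2X$/$R^2Y$ (fractions of X- and y-variance explained) and $Q^2$
(y-variance predicted under stratified 7-fold cross-validation; fold count
and seed configurable). Columns are mean-centred and unit-variance scaled
by default (`"pareto"` and `"none"` available): UV scaling is the common
default for metabolomic feature tables, where intensity scales span
decades. By construction the predictive scores are exactly orthogonal to
every orthogonal score vector, and the explained plus residual X sums of
squares add to the total — both are asserted in the test suite.

With thousands of ions and ~100 samples, $R^2Y \approx 1$ is expected and
carries no evidence; $Q^2$ is the number to read.

**LLE.** `lle()` embeds samples (over the candidate ions, standardised) by
reconstructing each sample from its $k$ nearest Euclidean neighbours with
weights constrained to sum to one, then taking the bottom non-constant
eigenvectors of $(I-W)^\top(I-W)$. Defaults $k = 12$ and Tikhonov
regularisation $10^{-3}$ (relative to the local Gram trace) are surfaced in
the interface; the regulariser also absorbs duplicate points. LLE is an
embedding, not a clustering: the function returns 2-D coordinates and
leaves any cluster assignment to the caller.

## The classifier

`c45()` grows a binary gain-ratio decision tree on the candidate-ion
intensities. Candidate thresholds for a continuous attribute are the
midpoints between consecutive distinct sorted values; only splits whose
information gain reaches the mean gain of all size-admissible candidates
compete (the classic gain-ratio guard against many-valued attributes), and
the highest gain ratio wins, ties to the smaller threshold and then to the
first ion in column order. Leaves predict the majority class; ties predict
case, deliberately favouring sensitivity in a detection setting.

Pruning is bottom-up subtree replacement: a subtree collapses to a leaf
when the pessimistic error of the leaf — $N$ times the upper
confidence bound (default confidence 0.25) of its binomial training error
rate — does not exceed the summed pessimistic errors of the subtree.
Defaults (`min_leaf = 2`, `prune_confidence = 0.25`) follow the common
open-source implementation of this algorithm family. Fractional routing of
missing values is intentionally not implemented: screening guarantees
candidates are detected in most samples, and zeros are treated as literal
intensities. `to_text()` prints the indented rule listing and
`parse_c45_text()` inverts it exactly.

## Evaluation protocol

The training split is evaluated by stratified k-fold cross-validation
(default $k=5$): each group is shuffled under a seed and dealt round-robin,
so per-fold class counts differ by at most one — 55 case / 50 control gives
five folds of exactly 11 + 10. A single seeded partition is used rather
than repeated re-draws. For each fold a tree is fitted on the rest and
evaluated on the fold; every training sample is scored exactly once.

Two protocol subtleties deserve attention:

* **Feature selection is outside the CV loop by default.** Candidates are
  screened once on the full training split and reused in every fold. This
  mirrors the screen-once workflow this package models, but it leaks
  selection information into the folds and biases CV estimates upward.
  `cross_validate(..., nested = TRUE)` re-runs the cascade inside each
  fold for an honest estimate; it is off by default for fidelity to the
  modelled protocol, and the independent test set remains the unbiased
  measurement either way.
* **Two SD conventions.** Per-fold metric SDs are computed under both the
  population ($/n$) and sample ($/(n-1)$) conventions, because published
  five-fold tables are ambiguous about which they use (we have seen both
  in the same table). The object carries both; `sd_convention` selects the
  one displayed, defaulting to sample.

Metrics are accuracy, sensitivity (case recall) and specificity (control
recall), as percentages. Display rounding is half-up to two decimals —
what `round_half_up()` implements — while unrounded values are retained
internally; accuracy is exactly the prevalence-weighted mix of sensitivity
and specificity.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the cascade assumes,
with ground truth:

* **Cohort composition.** Defaults: 87 case and 65 control subjects;
  `split_train_test()` with 55/50 training leaves a 32/15 test split.
* **Intensities.** Per ion, a base $\log_{10}$ mean drawn uniformly from
  $[3, 6]$ (ion intensities of $10^3$–$10^6$ counts, a realistic span for
  TOF feature tables) and a $\log_{10}$ SD from $[0.15, 0.35]$; intensities
  are log-normal. The log-normal choice matches the pipeline's use of log
  fold changes; it is a modelling assumption of the generator, not a claim
  about real urine.
* **Dropout.** Each observation is zeroed independently with a per-ion
  probability drawn from $[0.05, 0.6]$, so roughly one in five background
  ions fails the detection filter outright and the survivor set thins
  further near the boundary. Markers use a fixed low dropout (0.05):
  planted markers model reliably detected ions.
* **Markers.** `n_markers` ions (default 6) get their case-group mean
  shifted by $\log_{10}(\text{fold})$, the linear fold drawn from
  `marker_fold_range` (default 5–15, bracketing the tenfold effect used in
  the recovery tests).
* **Labels.** Retention times uniform in 0.5–30 min, m/z in 50–1000,
  purely for label realism.

What the generator does **not** emulate: chromatographic drift, batch and
QC-injection structure, correlated ions (isotopes, adducts, in-source
fragments), osmolality normalisation, or heavy-tailed intensity noise.
Passing recovery tests therefore show the cascade is correct under its own
assumptions — independent log-normal ions with planted shifts — not that it
would behave identically on real profiles, where correlated features and
batch effects can inflate the false-positive rate.

A consequence worth stating: with several thousand truly null ions at the
default thresholds, on the order of one null ion per cohort passes all
four stages (an AUC of 0.7 is about 3.5 null SDs at $n = 55/50$, and the
stages are correlated because they read the same group difference). The
recovery guarantee tested is therefore *no false negatives* for strong
(tenfold) markers, alongside a false-positive count that stays two orders
of magnitude below $\alpha \cdot n_\text{ions}$.

## Problem sizes and determinism

The test suite and the reproduction script run cohorts of 105–152 samples
with 400–5000 ions, Gaussian-fit recovery at $10^5$ draws, permutation
oracles at $10^5$ relabellings, and five-seed recovery sweeps — sizes at
which every statistical check has comfortable resolution while a full run
stays in the tens of seconds on a single core. All randomness flows through
explicit integer seeds; `simulate_cohort()` and `run_pipeline()` are
bit-reproducible under a fixed configuration, and every seeded helper
restores the caller's RNG state.

## A complete run

```{r pipeline}
cfg <- pipeline_config(
  cohort = cohort_config(n_ions = 2000, marker_fold_range = c(10, 10),
                         seed = 11)
)
report <- run_pipeline(cfg)
report
```

The report prints the screening funnel, the candidate table (detection
counts per group, fold change, p, AUC), marker recovery against the planted
truth, the per-fold CV table with mean ± SD, the final tree's rule listing,
and the independent-test metrics with their confusion counts.

## Known limitations

* The cascade's stage-3 filter applies raw p-values; with very large ion
  counts the candidate list before the AUC filter grows linearly in
  $\alpha \cdot n_\text{ions}$.
* `opls()` supports a single predictive component (the two-class case);
  multi-class OPLS-DA is out of scope.
* The tree handles continuous attributes only — categorical covariates
  (sex, smoking status) would need a different splitter.
* CV uses a single seeded partition; repeated CV would tighten the SD
  estimates but is not part of the modelled protocol.
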