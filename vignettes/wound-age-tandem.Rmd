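---
title: "Wound-age estimation from muscle metabolomics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wound-age estimation from muscle metabolomics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundage)
```

## The problem and the modelling strategy

After a blunt-force muscle contusion, the tissue metabolome changes in a
structured, time-dependent way: inflammatory lipid mediators, amino acids
and nucleotide catabolites rise and fall on different schedules.
`woundage` turns those changes into an estimate of the time since injury,
expressed as one of seven wound-age windows between 4 and 48 hours.

The estimation problem is deliberately treated as *classification into
windows*, not regression onto hours.  Adjacent sampling times (e.g. 24 and
28 h) are metabolically near-identical, so a regression line would imply
precision the data cannot support; windows chosen from the observed
grouping structure (4, 8, 12, 16–20, 24–32, 36–40, 44–48 h) carry the
uncertainty honestly.

The pipeline has three stages:

1. **Screening.**  For each coarse post-injury phase (I: 4–12 h,
   II: 16–32 h, III: 36–48 h), a two-class OPLS-DA against the control
   group yields per-feature VIP scores, and a feature-wise two-sided Welch
   t-test on log areas yields p-values, Benjamini–Hochberg-adjusted across
   all features of that comparison.  Features with `VIP > 1` and
   `q < 0.05` are candidates.  The union of the three screens is the
   level-1 panel; each phase's own screen (restricted to the union) is its
   level-2 panel.
2. **Reduction.**  Within each classifier node, log areas of the node's
   panel are Z-scored with training-set statistics and projected to two
   dimensions by PLS-DR: the first two NIPALS PLS2 latent variables of the
   standardized features against the one-hot class encoding.  Two
   supervised coordinates are enough for the phase contrasts and make the
   decision surfaces directly plottable.
3. **Tandem classification.**  A first-level node assigns the coarse
   phase; the matching second-level node assigns the final window.  Every
   node trains four candidates — logistic regression, an RBF SVM with
   `C = 1.5`, a 128-tree random forest and a (32, 32) multilayer
   perceptron — on the 2-D training coordinates of a stratified 70/30
   split, and keeps the candidate with the best validation accuracy.

## The chemometrics core

`opls_fit` implements multiclass OPLS-DA by orthogonal signal correction:
before each orthogonal component, the current x-loading is deflated by its
projection onto an orthonormal basis of `X'Y`, leaving a direction of
systematic x-variation uncorrelated with the classes; the filtered matrix
then gets an ordinary NIPALS PLS2 fit with (by default) one predictive
component per class contrast (`A_pred = classes − 1`) and one orthogonal
component.  With `A_orth = 0` the model reduces exactly to `pls_nipals`,
which is tested against the closed-form least-squares fit at full rank.

Model quality is reported as `R²Y` on the fitted class matrix and `Q² =
1 − PRESS/SS_Y` from stratified 7-fold cross-validation (folds seeded and
dealt round-robin within each class).  Significance comes from two
complements: a label-permutation test (refit under shuffled labels;
compare `Q²` distributions) and CV-ANOVA, the F-test
`F = ((SS_Y − PRESS)/A) / (PRESS/(N − A − 1))` with `A` the total number
of fitted components, clipped at `F = 0` so a model no better than the
mean yields `p ≈ 1`.

VIP is computed over predictive components only
(`VIP_j = sqrt(p · Σ_a SS_a w_ja²/Σ_a SS_a)`); its normalization
`mean(VIP²) = 1` is asserted on every fitted model, which makes the
conventional `VIP > 1` threshold a statement about above-average
contribution.

## What the synthetic generator emulates

`synthetic_config()` encodes the emulated design: a control group plus
twelve contusion time points (4–48 h in 4-h steps) with nine replicates
(117 study samples), pooled QC injections whose expected profile is the
study grand mean with noise SD `within_sd/4`, and an external test set
drawn uniformly over the time points with hidden labels.

Peak areas are log-normal: positive, heavy-tailed, multiplicative noise —
the standard working model for chromatographic peak areas.  The 43 panel
metabolites follow four trajectory archetypes cycled by panel index
(early-peak, mid-peak, late-rise, monotone-fall), so every phase contrast
and every within-phase contrast has informative features.  Archetype
phase profiles are built with equal adjacent-phase gaps of 1.1 log units,
and the within-phase substructure is a linear ramp whose total swing is
that gap divided by `phase_gap`; between-phase mean differences therefore
exceed within-phase differences by exactly the configured factor
(default 3).  Background features (default 500) share one
label-independent log-normal law and act as the true-negative set for the
screen.

Default noise and effect sizes (`within_sd = 0.25`, `effect_scale = 1`)
were chosen once, from a design-time power argument, to reproduce the
qualitative separability the analysis assumes: with ~43 informative
features and an adjacent-window per-feature shift of ~0.18 log units, the
multivariate separation between adjacent windows is several within-group
standard deviations — clearly separable phases, harder within-phase
windows (the 4 h vs 8 h contrast is the typical error mode).  What the
generator does *not* emulate: retention-time drift, batch effects,
missing values, censored low-intensity peaks, or inter-animal covariance
between metabolites.  Passing tests on synthetic data therefore validate
the *pipeline logic and its statistical calibration*, not instrument-level
robustness on real data.

## Numerical and design choices

* **Total-area normalization** (each row rescaled to the cohort median
  total) is the most common metabolomics convention for the unstated
  "normalization of peak areas"; it is off by default for synthetic data,
  which has no injection-amount variation, and is applied before any
  split when enabled.
* **Z-scores use the population (1/n) SD.**  Constant training columns
  error by default; the screening path drops them and records the drop.
* **Leakage discipline.**  Scalers and reducers are fitted on training
  rows only; validation/external rows are always transformed with frozen
  parameters.  A dedicated test modifies validation content and asserts
  the fitted parameters are bit-identical.
* **Welch t-test on log areas** is the univariate screen: intensities are
  approximately log-normal and group variances need not be equal.  BH
  adjustment is applied within one comparison, not across comparisons.
* **Split rule**: per class, `round(0.7 n)` training samples, clamped so
  both sides are non-empty; stratification is by leaf window so both
  tandem levels see balanced splits.  The second level is trained on the
  same split, restricted to each coarse group's rows.
* **Tie-breaking in model selection** favours the later candidate in the
  order LR < SVM < RF < MLP (the deeper model), so a toy problem all four
  solve perfectly selects the MLP.
* **The MLP** is a compact base-R implementation: ReLU hidden layers
  (32, 32), softmax cross-entropy with L2 penalty `1e-4`, full-batch Adam
  at `1e-3`, and an adaptive schedule that divides the rate by 5 after 10
  non-improving iterations (tolerance `1e-4`), stopping below `1e-6` or
  at 3000 iterations.  Fits are deterministic given the seed.
* **Degenerate inputs.**  In the noise-free limit a node's feature block
  within one phase is numerically rank-1; PLS-DR then falls back to one
  latent variable with a zero second coordinate instead of failing, which
  preserves the recovery property (internal accuracy exactly 1 as
  `within_sd → 0`).
* **Serialization** is text-only: a YAML manifest plus per-node CSVs of
  scaler/reducer parameters and the 2-D training data; classifiers are
  refitted deterministically on load, so a round-tripped bundle predicts
  identically.
* **Macro one-vs-rest AUC** (midrank-tied Mann–Whitney per class,
  averaged) is the multiclass AUC convention; it is descriptive only and
  never drives model selection.

## Problem sizes used in the tests

Most tests run the full panel with a 50-feature background block
(93 features × 117 samples); the screening-calibration and headline
tandem checks use the full default design (543 features × 117 samples).
The tandem-vs-flat comparison uses ten split seeds on one generated
study; the null-calibration suite uses a single `effect_scale = 0` study
plus 50 small permutation draws for CV-ANOVA.  These sizes were chosen as
the smallest designs at which the properties under test are
non-degenerate.

## Known limitations

* The OPLS-DA component counts, like SIMCA's auto-selection, are not
  estimated from the data; defaults are `classes − 1` predictive and one
  orthogonal component.
* The screen's VIP comes from a two-class (phase vs control) OPLS-DA; a
  global multi-class screen would rank features differently.
* Windows are fixed by the grouping scheme; the package does not learn
  the window boundaries.
* Synthetic external samples share the generator's noise law; real
  external cohorts (new animals, new batches) are harder in ways the
  generator does not model, and external accuracy on real data should be
  expected to drop accordingly.
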