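---
title: "Stable iterative variable selection: model, design and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stable iterative variable selection: model, design and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sivsel)
```

## The problem

An L1-penalized (LASSO) logistic regression performs embedded feature
selection: at the cross-validated penalty, most coefficients are exactly
zero and the nonzero set is "the model's features". In high-dimensional
biomedical data (expression arrays, RNA-seq, clinical trial tables) that
set is notoriously unstable — refitting with nothing changed but the
random assignment of samples to cross-validation folds can change which
features survive, by tens of features at a time. Downstream biology is
then built on an accident of the fold assignment.

`sivsel` stabilizes the selection by *aggregating over fold assignments*
instead of trusting any single one. The procedure has four stages:

1. **Preprocessing.** Zero-variance numeric features and single-level
   categorical features are removed; samples with missing values are
   dropped; categoricals are reference-coded into indicators; every
   column is standardized to mean 0, sample standard deviation 1
   (n − 1 denominator), so coefficients are on a common scale and
   comparable across features.
2. **Iterative model building.** k models (default 100) are fit with the
   same learner but different fold-assignment seeds, and every
   coefficient vector is collected, along with each model's training
   AUROC.
3. **Importance scoring.** For each feature, let c* be the vector of its
   *nonzero* coefficients across the k runs. The variable-importance
   score is

   VIMP = I(c*) × mabs(c*) × |c*| / (1 + IQR(c*)),

   where I(c*) is 1 if all entries of c* share one sign and 0 otherwise,
   mabs is the median absolute value, |c*| the selection count, and IQR
   the interquartile range of c*. Features selected often, with a
   consistent sign, a large typical magnitude and little spread score
   high; a feature never selected, or selected with both signs, scores
   exactly 0.
4. **Recursive elimination and cutoff.** Features with positive VIMP are
   kept; the rest are discarded. The survivors are then removed one at a
   time in *increasing* VIMP order; after each removal, r models
   (default 100) are refit under fresh fold seeds and their training
   AUROCs recorded. With x̃min and x̃max the minimum and maximum of the
   per-step median AUROC, the suggested cutoff is

   cutoff = (1 − γ) × (x̃max − x̃min) + x̃min,

   a minimum acceptable training AUROC. The selected set is the smallest
   remaining set whose median AUROC still meets the cutoff (scanning
   from the smallest set backward), i.e. maximal shrinkage subject to
   the AUROC bar. Higher strictness γ lowers the bar and retains fewer
   features; the default γ = 0.01 is deliberately loose.

The cutoff is a *post-hoc* knob: `suggest_cutoff()` (and the `suggest`
CLI subcommand) re-derive the selection from a stored elimination trace
at any γ without refitting anything.

## The internal learner

The default learner is an L1-penalized logistic regression
(`glmnet::cv.glmnet`, α = 1, binomial family) with the penalty chosen by
V-fold cross-validation (default V = 10) on a given fold assignment.
Several conventions had to be pinned where more than one was defensible:

* **Penalty grid.** 100 log-spaced values from the data-derived maximal
  penalty — the smallest penalty with an all-zero solution, analytically
  max|xⱼ'(y − ȳ)|/n on standardized columns — down to 10⁻³ of it.
* **Penalty rule.** The grid member minimizing mean cross-validated
  binomial deviance (the "lambda.min" convention), not the one-standard-
  error rule. This maximizes per-run sensitivity; the ensemble
  aggregation is what provides the stability.
* **Fold stratification.** Folds are class-stratified (within each class,
  sizes differ by at most one). Unstratified folds can go degenerate on
  small or imbalanced data; at the sample sizes this method targets the
  difference is immaterial, but it is a deliberate deviation from the
  common unstratified default.
* **"Nonzero".** A coefficient counts as nonzero when |coef| ≥ 10⁻⁸.
  Coordinate-descent solvers differ in returning exact zeros versus tiny
  residuals; a fixed threshold makes the zero pattern
  solver-independent.
* **Convergence tolerance.** The path solver runs at `thresh = 1e-5`.
  The chosen penalty and the nonzero pattern are unchanged relative to
  tighter tolerances on data of the scale exercised here, while fitting
  is several times faster; coefficient values move by ~10⁻³, far below
  anything the median/IQR aggregation can notice.
* **Degenerate single-column fits.** The L1 path solver requires at
  least two columns, so the last elimination step (one remaining
  feature) uses an unpenalized univariate logistic fit
  (`chosen_penalty = 0`). Only that step's AUROC distribution is
  affected, and AUROC is invariant to the monotone link anyway.

Any learner can replace the default: the contract is
`fit(X, y, fold_seed) → coefficients + training scores`, with the zero
pattern defining "selected". A learner returning a wrong-length
coefficient vector is rejected as a contract violation.

## Numerical conventions in the score

* Median of an even-length vector: mean of the two middle order
  statistics.
* IQR: Q3 − Q1 with linear-interpolation ("type 7") quantiles. On small
  selection counts this choice materially changes the score, so it is
  pinned and oracle-tested.
* The IQR is taken over the signed nonzero coefficients as the score is
  written; for sign-consistent vectors (the only ones with positive
  score) this equals the IQR of the absolute values.
* Count-zero features get score 0 rather than "undefined", keeping the
  table total.
* Ties in the score are broken by higher selection count, then
  lexicographic feature name, so the elimination order — and hence the
  whole downstream trace — is deterministic.

## Reproducibility and seeds

Every source of randomness derives from one master seed through named
streams (`derive_seeds()`): iteration j of the model-building stage,
repeat j of elimination step s, and the study harness's shared fold-seed
sequence each get an independent, reproducible seed. Two runs with the
same data, configuration and master seed produce byte-identical result
JSON. Failed fits (non-convergence) are recorded and excluded — the
selection count denominator is the number of *successful* runs — with a
hard error if more than 10% fail.

## AUROC in the elimination step

Each elimination-step AUROC is computed from the refit model's predicted
probabilities on the full training set, anchoring the cutoff as a
minimum acceptable *training* AUROC. This is optimistic by construction;
`rfe_auroc = "out_of_fold"` switches to cross-validated (pre-validation)
scores for a less optimistic trace. x̃min/x̃max range over the per-step
*median* AUROCs, the natural summary of each step's box of r values;
step 0 (no removal) is part of the range, so the full positive-VIMP set
can win.

## The synthetic-data generator

The generator produces the two regimes the method targets with one
model: features are zero-mean Gaussians; the `n_informative` informative
columns are independent with true logit coefficients of magnitude
`effect_size` and alternating sign (so both signs of the consistency
indicator are exercised); noise columns come in equicorrelated blocks
(default correlation 0.3, block size 10) to exercise the collinearity
weakness of L1 selection; labels are Bernoulli(sigmoid(Xβ + intercept)).
Setting `categorical_fraction > 0` tertile-bins the last columns into
3-level categoricals, emulating a clinical table; 0 gives the omics-like
p ≫ n regime. Informative features are kept independent so that
ground-truth recovery is well-posed.

What the generator does *not* emulate: count distributions and
library-size effects of sequencing data, batch effects, heavy-tailed or
skewed markers, missing-not-at-random patterns, and survival outcomes.
Tests passing on this generator demonstrate the machinery and its
statistical behaviour under a correctly specified logistic model, not
performance on any particular real platform.

Default study conditions used by the heavier checks and the acceptance
script: 300 training and 200 validation samples, p = 300 with 8
informative features at effect size 1.5, k = 50 iterations, r = 25
elimination repeats, 20 repeated fits per study arm. These sizes retain
the qualitative behaviour of the full-scale defaults (k = r = 100) while
keeping a complete run in the minutes range.

## Design choices that were genuinely open

* **Cutoff → feature-set mapping.** The cutoff defines a minimum
  acceptable AUROC but not, by itself, which step's feature set to
  return. We scan from the smallest remaining set backward and return
  the first whose median AUROC meets the cutoff: maximal reduction
  subject to the bar. An alternative (thresholding features by VIMP
  value at the cutoff's step) gives the same answer whenever medians are
  monotone in the trace but can differ on non-monotone traces;
  bit-compatibility with other implementations of the idea is not
  claimed.
* **Standardizing indicator columns.** Dummy columns from categoricals
  are standardized like numeric columns, because the stated purpose of
  scaling is cross-feature coefficient comparability — which the score
  aggregation depends on.
* **Standardization once, on the full training set.** Scaling statistics
  are computed once before model building, not inside each fold. The
  alternative (per-fold re-standardization) changes little at these
  sample sizes but would make coefficients incomparable across steps.
* **Missing values.** Samples with any missing value are dropped (the
  learner cannot consume them); `on_missing = "error"` is available when
  silent sample loss is unacceptable. Imputation belongs upstream of
  this package.

## Evaluation statistics

The study harness (`run_study()`) replicates a two-arm design: many
plain cross-validated fits versus many fits restricted to the stable
selection, sharing the fold-seed sequence so that per-seed pairs are
well-defined. Its statistics are implemented with pinned conventions and
oracle tests:

* AUROC by midranks (Mann–Whitney; ties count ½).
* Paired DeLong comparison of correlated AUROCs via placement values,
  two-sided normal p; zero-variance differences degenerate to p = 1
  (equal AUROCs) or 0.
* Paired Wilcoxon signed-rank on feature counts: zeros dropped, midranks
  for ties, exact null (convolution over the realized rank multiset) up
  to 25 nonzero differences, tie-corrected normal approximation beyond,
  no continuity correction.
* Stability summaries: global intersection and union, |∩|/|∪|, and mean
  pairwise Jaccard; the all-empty case is defined as perfectly stable
  (Jaccard 1).

No multiplicity correction is applied to the per-seed DeLong p-values;
the harness reports the full vector and its median.

## Known limitations

* Binary classification only; multinomial, continuous and survival
  responses are out of scope.
* Strongly correlated *informative* features still inherit LASSO's
  behaviour of splitting credit across a block; the sign-consistency
  indicator can then zero out genuinely informative features whose
  coefficient sign flips between runs.
* The training-set AUROC anchoring the cutoff is optimistic; with very
  small n the trace can saturate at 1.0 for many steps, making the
  cutoff insensitive until real signal is removed (the out-of-fold
  option mitigates this).
* γ is subjective by design; the package suggests, it does not decide.
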