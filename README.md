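# sivsel — stable iterative variable selection

`sivsel` selects a compact, *reproducible* feature set for binary
classification from tabular data (omics matrices, clinical tables). It
addresses a well-known failure mode of L1-penalized (LASSO) logistic
regression: the set of features with nonzero coefficients depends on the
random assignment of samples to cross-validation folds, so two analysts
fitting "the same model" on the same data routinely report different
biomarker panels.

Instead of trusting one fold assignment, `sivsel`:

1. fits k cross-validated L1 logistic models under k different fold
   seeds and collects all coefficients;
2. scores every feature by

   **VIMP = I(c\*) · mabs(c\*) · |c\*| / (1 + IQR(c\*))**,

   where c\* is the vector of the feature's nonzero coefficients across
   runs, I(c\*) indicates sign-consistency, mabs is the median absolute
   value, |c\*| the selection count and IQR the interquartile range —
   features picked often, with stable sign, large typical effect and
   little spread score high;
3. eliminates positive-VIMP features one at a time in increasing-VIMP
   order, refitting an ensemble of r models after each removal and
   recording training AUROCs;
4. suggests a cutoff **(1 − γ)(x̃max − x̃min) + x̃min** on the per-step
   median AUROC (strictness γ ∈ (0,1), default 0.01) and returns the
   smallest remaining set that still meets it.

The package also ships a synthetic-data generator with known informative
features, evaluation statistics (midrank AUROC, paired DeLong test,
exact paired Wilcoxon, selection-stability summaries), a two-arm study
harness, plotting helpers and a command-line interface.

## Worked example

```r
library(sivsel)

spec <- synthetic_spec(n_train = 200, p = 100, n_informative = 5,
                       effect_size = 2.0, seed = 11)
dataset <- generate_dataset(spec)
dataset
#> <sivs_dataset> 200 samples x 100 features; classes: control=107, case=93; 5 informative

config <- sivs_config(iterations = 20, rfe_repeats = 10, master_seed = 3)
result <- select_features(dataset, config)
result
#> <sivs_result> status: ok
#>   iterations: 20 | positive-VIMP features: 37
#>   selected (15): feat_0002, feat_0003, feat_0005, feat_0004, feat_0001, feat_0026, feat_0040, feat_0025, feat_0014, feat_0099, ...
#>   AUROC cutoff: 0.9969 at gamma = 0.01

intersect(result$selected_features, dataset$truth)
#> [1] "feat_0002" "feat_0003" "feat_0005" "feat_0004" "feat_0001"
```

Reading the output: 37 of the 100 features had a positive importance
score (selected at least once, with consistent sign, across the 20
fits); the elimination trace's cutoff keeps the smallest remaining set
whose median training AUROC still meets 0.9969 — 15 features, including
all five of the planted informative ones, with the loose default
strictness γ = 0.01 (a higher γ such as 0.05 cuts deeper).
`write_result()` serializes everything (ensemble,
importance table, elimination trace, cutoff, seeds) to versioned JSON;
`suggest_cutoff()` re-derives the selection at any other strictness from
the stored trace without refitting.

The same pipeline from a shell:

```sh
inst/cli/sivsel simulate --n-train 200 --p 100 --n-informative 5 \
    --effect-size 2 --seed 11 --output data.csv
inst/cli/sivsel run --input data.csv --iterations 20 --rfe-repeats 10 \
    --seed 3 --output result.json
inst/cli/sivsel suggest --result result.json --gamma 0.05
inst/cli/sivsel report --result result.json --outdir report/
```

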