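# Small fixtures built in code.

# A tiny, well-separated two-class dataset for fast pipeline runs.
tiny_dataset <- function(n = 80, p = 12, n_informative = 3, effect = 2.5,
                         seed = 42, ...) {
  generate_dataset(synthetic_spec(n_train = n, p = p,
                                  n_informative = n_informative,
                                  effect_size = effect, seed = seed, ...))
}

fast_config <- function(...) {
  args <- modifyList(list(iterations = 6, rfe_repeats = 4, cv_folds = 5,
                          master_seed = 7), list(...))
  do.call(sivs_config, args)
}

# An ensemble with a hand-chosen coefficient matrix (runs x features).
ensemble_from_matrix <- function(coef, feature_names = colnames(coef)) {
  colnames(coef) <- feature_names
  structure(list(coef = coef,
                 meta = data.frame(run = seq_len(nrow(coef)),
                                   seed = seq_len(nrow(coef)),
                                   penalty = 0.1,
                                   train_auroc = 0.9,
                                   ok = TRUE),
                 feature_names = feature_names),
            class = "sivs_ensemble")
}

# An elimination trace with prescribed per-step median AUROCs; features
# are removed in the order given.
trace_from_medians <- function(medians, features = NULL) {
  m <- length(medians)
  features <- features %||% sprintf("f%02d", seq_len(m))
  elim <- rev(features)
  steps <- lapply(seq_len(m) - 1L, function(s) {
    remaining <- features[seq_len(m - s)]
    list(step = s,
         removed_feature = if (s == 0) NA_character_ else elim[s],
         remaining_features = remaining,
         auroc_samples = rep(medians[s + 1], 3),
         median_auroc = medians[s + 1])
  })
  structure(list(steps = steps, elimination_order = elim),
            class = "sivs_rfe_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
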