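# Shared study-scale computation, built once and reused by the heavier
# tests: five end-to-end selections under different master seeds on the
# same high-dimensional synthetic dataset, plus the two-arm comparison
# study reusing the first selection.

.study_cache <- new.env(parent = emptyenv())

study_fixture <- function() {
  if (!is.null(.study_cache$fx)) return(.study_cache$fx)
  spec <- synthetic_spec(n_train = 300, n_valid = 200, p = 300,
                         n_informative = 8, effect_size = 1.5, seed = 2026)
  full <- generate_dataset(spec)
  parts <- split_train_valid(full, spec$n_valid, seed = 2026)
  configs <- lapply(1:5, function(s)
    sivs_config(iterations = 50, rfe_repeats = 25, cv_folds = 10,
                master_seed = s))
  results <- lapply(configs, function(cfg) select_features(parts$train, cfg))
  study <- run_study(parts$train, parts$valid, n_runs = 20,
                     config = configs[[1]], sivs_result = results[[1]])
  .study_cache$fx <- list(spec = spec, parts = parts, results = results,
                          study = study)
  .study_cache$fx
}
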