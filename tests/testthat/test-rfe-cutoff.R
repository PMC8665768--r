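test_that("cutoff arithmetic follows the strictness formula", {
  tr <- trace_from_medians(c(0.9, 0.85, 0.7, 0.6))
  cut <- suggest_cutoff(tr, 0.01)
  expect_equal(cut$x_min, 0.6)
  expect_equal(cut$x_max, 0.9)
  expect_equal(cut$cutoff, 0.99 * 0.3 + 0.6)

  # all-equal medians collapse the range; the final single-feature set wins
  tr_flat <- trace_from_medians(rep(0.8, 4))
  cut_flat <- suggest_cutoff(tr_flat, 0.01)
  expect_equal(cut_flat$cutoff, 0.8)
  expect_length(cut_flat$selected_features, 1)

  # higher strictness lowers the bar and keeps fewer features
  cuts <- vapply(c(0.01, 0.3, 0.6, 0.99), function(g)
    suggest_cutoff(tr, g)$cutoff, numeric(1))
  expect_true(all(diff(cuts) < 0))
  expect_true(all(cuts >= cut$x_min & cuts <= cut$x_max))

  expect_error(suggest_cutoff(tr, 0), "gamma")
  expect_error(suggest_cutoff(tr, 1), "gamma")
})

test_that("the cutoff maps to the smallest qualifying remaining set", {
  # medians rise back up late: the last step meeting the bar wins
  tr <- trace_from_medians(c(0.9, 0.89, 0.7, 0.88, 0.6))
  cut <- suggest_cutoff(tr, 0.05)
  expect_equal(cut$cutoff, 0.95 * 0.3 + 0.6)
  # qualifying steps are medians >= 0.885: steps 0 (0.9), 1 (0.89); step 3
  # (0.88) just misses; smallest qualifying set is step 1's
  expect_equal(cut$step_index, 1)
  expect_length(cut$selected_features, 4)
})

test_that("elimination trace has the pinned structure and determinism", {
  d <- tiny_dataset(n = 120, p = 15, n_informative = 3, seed = 21)
  pp <- preprocess(d)
  cfg <- fast_config(iterations = 10, rfe_repeats = 5, master_seed = 13)
  vt <- build_vimp_table(run_iterations(pp$dataset, cfg))
  tr <- run_rfe(pp$dataset, vt, cfg)

  sizes <- vapply(tr$steps, function(s) length(s$remaining_features),
                  integer(1))
  m <- sum(vt$vimp > 0)
  expect_equal(sizes, seq(m, 1))
  expect_equal(vapply(tr$steps, `[[`, numeric(1), "step"), 0:(m - 1))
  # elimination order is increasing importance under the pinned tie-break
  expect_equal(tr$elimination_order, rev(vt$feature[vt$vimp > 0]))
  expect_true(is.na(tr$steps[[1]]$removed_feature))
  expect_equal(vapply(tr$steps[-1], `[[`, character(1), "removed_feature"),
               tr$elimination_order[seq_len(m - 1)])
  for (s in tr$steps) {
    expect_equal(s$median_auroc, median(s$auroc_samples))
    expect_length(s$auroc_samples, cfg$rfe_repeats)
  }

  tr2 <- run_rfe(pp$dataset, vt, cfg)
  expect_identical(tr, tr2)
})

test_that("elimination needs at least two surviving features", {
  coef <- rbind(c(0.7, 0, -0.2), c(0.8, 0, 0.3))
  ens <- ensemble_from_matrix(coef, c("keep", "never", "flip"))
  vt <- build_vimp_table(ens)
  d <- tiny_dataset(n = 60, p = 3, seed = 30)
  names(d$X) <- c("keep", "never", "flip")
  d$feature_names <- names(d$X)
  expect_error(run_rfe(preprocess(d)$dataset, vt, fast_config()),
               "at most one stable feature")
})

test_that("removing signal features costs AUROC; removing noise does not", {
  d <- generate_dataset(synthetic_spec(n_train = 200, p = 40,
                                       n_informative = 4, effect_size = 2.5,
                                       seed = 55))
  pp <- preprocess(d)
  cfg <- sivs_config(iterations = 15, rfe_repeats = 8, master_seed = 3)
  vt <- build_vimp_table(run_iterations(pp$dataset, cfg))
  expect_true(all(d$truth %in% vt$feature[vt$vimp > 0]))
  tr <- run_rfe(pp$dataset, vt, cfg)
  med <- vapply(tr$steps, `[[`, numeric(1), "median_auroc")
  sizes <- vapply(tr$steps, function(s) length(s$remaining_features),
                  integer(1))
  # the step where only the informative features remain performs like the
  # full positive-importance set
  truth_step <- which(vapply(tr$steps, function(s)
    setequal(s$remaining_features, d$truth), logical(1)))
  expect_length(truth_step, 1)
  expect_lt(abs(med[truth_step] - med[1]), 0.05)
  # stripping the signal down to one feature costs real performance
  expect_gt(med[truth_step] - med[length(med)], 0.05)
})

test_that("end-to-end selection returns a coherent result object", {
  d <- tiny_dataset(n = 100, p = 12, n_informative = 3, seed = 61)
  cfg <- fast_config(iterations = 8, rfe_repeats = 4, master_seed = 17)
  res <- select_features(d, cfg)
  expect_s3_class(res, "sivs_result")
  expect_equal(res$status, "ok")
  expect_gt(length(res$selected_features), 0)
  # selection never leaves the positive-importance set, which never
  # leaves the union of per-run selections
  vt <- res$vimp_table
  expect_true(all(res$selected_features %in% vt$feature[vt$vimp > 0]))
  union_sel <- colnames(res$ensemble$coef)[colSums(abs(res$ensemble$coef)
                                                   >= 1e-8) > 0]
  expect_true(all(res$selected_features %in% union_sel))
})

test_that("a signal-free dataset reports no stable features, not a crash", {
  # a learner facing pure noise at tiny n selects nothing in most runs;
  # engineered here via an ensemble aggregation check on an all-zero fit
  coef <- matrix(0, 3, 4, dimnames = list(NULL, sprintf("f%d", 1:4)))
  vt <- build_vimp_table(ensemble_from_matrix(coef))
  expect_true(all(vt$vimp == 0))

  d <- generate_dataset(synthetic_spec(n_train = 40, p = 6,
                                       n_informative = 0, seed = 3))
  cfg <- fast_config(iterations = 5, rfe_repeats = 3, master_seed = 2)
  res <- select_features(d, cfg)
  expect_true(res$status %in% c("ok", "no_stable_features", "single_feature"))
  if (res$status != "ok") {
    expect_null(res$rfe_trace)
    expect_lte(length(res$selected_features), 1)
  }
})
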