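# Stability/performance study harness: many plain cross-validated L1 fits
# versus many fits restricted to the stable selection, sharing the same
# fold-seed sequence so per-seed AUROC pairs are well-defined.

#' Compare plain repeated fits with fits restricted to the stable selection
#'
#' Arm 1 fits `n_runs` cross-validated L1 logistic models on the training
#' set, each under a fresh fold seed, recording the selected features and
#' the validation AUROC. Arm 2 performs one stable selection
#' ([select_features()]) on the training set and then refits the same
#' `n_runs` models restricted to the selected columns, reusing arm 1's
#' fold-seed sequence. Per-seed paired DeLong tests compare validation
#' AUROCs across arms; a paired Wilcoxon compares feature counts.
#'
#' @param train,valid Raw [sivs_dataset()]s sharing a feature space; both
#'   classes present in both.
#' @param n_runs Number of repeated fits per arm.
#' @param config A [sivs_config()] driving both the selection and the
#'   repeated fits.
#' @param sivs_result Optional precomputed [select_features()] result for
#'   `train` under `config`, to avoid refitting the selection stage.
#' @return An object of class `sivs_study`: `sivs_result`, per-arm lists
#'   (`sets`, `feature_counts`, `valid_auroc`), `summary` (data.frame of
#'   max/median/mean/min/sd per arm and metric), `stability` (per-arm
#'   [stability_summary()]), `delong` (data.frame `seed`, `auroc_plain`,
#'   `auroc_sivs`, `z`, `p`), `delong_median_p`, `wilcoxon_p`.
#' @export
run_study <- function(train, valid, n_runs = 100, config = sivs_config(),
                      sivs_result = NULL) {
  stopifnot(inherits(train, "sivs_dataset"), inherits(valid, "sivs_dataset"))
  if (!setequal(train$feature_names, valid$feature_names))
    sivs_stop("train and valid must share a feature space",
              class = "sivsel_data_error")
  prep <- preprocess(train, config$on_missing)
  valid_p <- apply_preprocess(valid, prep$report)
  Xt <- dataset_matrix(prep$dataset)
  Xv <- dataset_matrix(valid_p)[, colnames(Xt), drop = FALSE]
  yt <- prep$dataset$y
  yv01 <- response_binary(valid_p$y, config$positive_class)
  seeds <- derive_seeds(config$master_seed, n_runs, stream = "study")
  learner <- make_learner(config)

  run_arm <- function(X_train, X_valid) {
    lapply(seq_len(n_runs), function(i) {
      fit <- learner(X_train, yt, seeds[i])
      sel <- selected_features(fit)
      eta <- drop(X_valid %*% fit$coefficients) + fit$intercept
      list(set = sel, count = length(sel),
           valid_scores = plogis(eta),
           valid_auroc = auroc(yv01, plogis(eta)))
    })
  }

  config_message(config, "study arm 1: ", n_runs, " plain fits")
  arm_plain <- run_arm(Xt, Xv)
  config_message(config, "study arm 2: stable selection + ", n_runs,
                 " restricted fits")
  sel_result <- sivs_result %||% select_features(train, config)
  stopifnot(inherits(sel_result, "sivs_result"))
  sel <- sel_result$selected_features
  if (length(sel) < 2)
    sivs_stop("stable selection kept fewer than two features; ",
              "the restricted arm cannot be fit",
              class = "sivsel_data_error")
  arm_sivs <- run_arm(Xt[, sel, drop = FALSE], Xv[, sel, drop = FALSE])

  extract <- function(arm, what) vapply(arm, `[[`, numeric(1), what)
  counts <- list(plain = extract(arm_plain, "count"),
                 sivs = extract(arm_sivs, "count"))
  aurocs <- list(plain = extract(arm_plain, "valid_auroc"),
                 sivs = extract(arm_sivs, "valid_auroc"))
  summarize <- function(v) c(max = max(v), median = median(v),
                             mean = mean(v), min = min(v), sd = sd(v))
  summary_df <- do.call(rbind, lapply(names(counts), function(arm) {
    data.frame(arm = arm,
               metric = c("feature_count", "valid_auroc"),
               rbind(summarize(counts[[arm]]), summarize(aurocs[[arm]])),
               row.names = NULL)
  }))

  delong <- do.call(rbind, lapply(seq_len(n_runs), function(i) {
    dl <- delong_paired_test(yv01, arm_plain[[i]]$valid_scores,
                             arm_sivs[[i]]$valid_scores)
    data.frame(seed = seeds[i], auroc_plain = dl$auroc_a,
               auroc_sivs = dl$auroc_b, z = dl$z, p = dl$p)
  }))
  wil <- paired_wilcoxon(counts$sivs, counts$plain)

  structure(list(
    sivs_result = sel_result,
    sets = list(plain = lapply(arm_plain, `[[`, "set"),
                sivs = lapply(arm_sivs, `[[`, "set")),
    feature_counts = counts,
    valid_auroc = aurocs,
    summary = summary_df,
    stability = list(plain = stability_summary(lapply(arm_plain, `[[`, "set")),
                     sivs = stability_summary(lapply(arm_sivs, `[[`, "set"))),
    delong = delong,
    delong_median_p = median(delong$p),
    wilcoxon_p = wil$p),
    class = "sivs_study")
}

#' @export
print.sivs_study <- function(x, ...) {
  cat("<sivs_study>", length(x$feature_counts$plain), "runs per arm\n")
  cat(format_study_table(x), sep = "\n")
  invisible(x)
}

# Plain-text comparison table (feature counts, validation AUROC,
# intersection/union sizes per arm).
format_study_table <- function(study) {
  s <- study$summary
  fmt <- function(arm, metric) {
    row <- s[s$arm == arm & s$metric == metric, ]
    sprintf("%7.3f %7.3f %7.3f %7.3f %7.3f",
            row$max, row$median, row$mean, row$min, row$sd)
  }
  c(sprintf("%-22s %7s %7s %7s %7s %7s", "", "max", "median", "mean",
            "min", "sd"),
    sprintf("%-22s %s", "plain feature count", fmt("plain", "feature_count")),
    sprintf("%-22s %s", "sivs  feature count", fmt("sivs", "feature_count")),
    sprintf("%-22s %s", "plain valid AUROC", fmt("plain", "valid_auroc")),
    sprintf("%-22s %s", "sivs  valid AUROC", fmt("sivs", "valid_auroc")),
    sprintf("plain  |intersect| = %d, |union| = %d",
            length(study$stability$plain$intersect),
            length(study$stability$plain$union)),
    sprintf("sivs   |intersect| = %d, |union| = %d",
            length(study$stability$sivs$intersect),
            length(study$stability$sivs$union)),
    sprintf("paired Wilcoxon p (feature counts) = %.3g", study$wilcoxon_p),
    sprintf("median paired DeLong p (valid AUROC) = %.3g",
            study$delong_median_p))
}
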