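# Recursive feature elimination over the positive-VIMP set, and the
# strictness cutoff that maps the elimination trace to a final feature set:
#
#   cutoff = (1 - gamma) * (x_max - x_min) + x_min
#
# with x_min/x_max the minimum and maximum of the per-step median training
# AUROC. The cutoff is the minimum acceptable AUROC over the training set;
# higher gamma lowers it and retains fewer features.

#' Recursive feature elimination ordered by increasing VIMP
#'
#' Starts from the features with positive VIMP. Step 0 refits
#' `config$rfe_repeats` models (distinct fold seeds) on the full starting
#' set; each later step permanently removes the lowest-VIMP remaining
#' feature and refits, recording every model's training-set AUROC
#' (out-of-fold AUROC when `config$rfe_auroc = "out_of_fold"`). The trace
#' ends when one feature remains. Fully deterministic in
#' `config$master_seed`.
#'
#' @param dataset A preprocessed [sivs_dataset()].
#' @param vimp_table A [build_vimp_table()] result for this dataset.
#' @param config A [sivs_config()].
#' @return An object of class `sivs_rfe_trace`: `steps` (list; each step
#'   has `step`, `removed_feature`, `remaining_features`, `auroc_samples`,
#'   `median_auroc`) and `elimination_order` (features in increasing-VIMP
#'   order).
#' @export
run_rfe <- function(dataset, vimp_table, config = sivs_config()) {
  stopifnot(inherits(dataset, "sivs_dataset"),
            inherits(vimp_table, "sivs_vimp_table"),
            inherits(config, "sivs_config"))
  positive <- vimp_table$feature[vimp_table$vimp > 0]
  if (length(positive) < 2)
    sivs_stop("recursive elimination needs at least two positive-VIMP ",
              "features; at most one stable feature was found",
              class = "sivsel_data_error")
  # vimp_table is sorted descending; eliminate from the bottom up
  elimination_order <- rev(positive)
  X <- dataset_matrix(dataset)[, positive, drop = FALSE]
  y <- dataset$y
  y01 <- response_binary(y, config$positive_class)
  r <- config$rfe_repeats
  m <- length(positive)
  learner <- make_learner(config)
  use_oof <- identical(config$rfe_auroc, "out_of_fold")
  steps <- vector("list", m)
  remaining <- positive
  for (s in seq_len(m) - 1L) {
    removed <- if (s == 0L) NA_character_ else elimination_order[s]
    if (s > 0L) remaining <- setdiff(remaining, removed)
    seeds <- derive_seeds(config$master_seed, r, stream = paste0("rfe_", s))
    Xs <- X[, remaining, drop = FALSE]
    aurocs <- unlist(run_map(config, seq_len(r), function(j) {
      fit <- tryCatch(learner(Xs, y, seeds[j]), error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      sc <- if (use_oof) fit$oof_scores else fit$train_scores
      auroc(y01, sc)
    }))
    n_fail <- sum(is.na(aurocs))
    if (n_fail > 0) {
      warning(n_fail, " of ", r, " elimination fits failed at step ", s,
              call. = FALSE)
      if (n_fail / r > 0.1)
        sivs_stop("more than 10% of elimination fits failed at step ", s,
                  class = "sivsel_data_error")
      aurocs <- aurocs[!is.na(aurocs)]
    }
    steps[[s + 1L]] <- list(step = s, removed_feature = removed,
                            remaining_features = remaining,
                            auroc_samples = aurocs,
                            median_auroc = median(aurocs))
    config_message(config, "rfe step ", s, ": |remaining| = ",
                   length(remaining), ", median AUROC = ",
                   signif(median(aurocs), 4))
  }
  structure(list(steps = steps, elimination_order = elimination_order),
            class = "sivs_rfe_trace")
}

#' Suggest a feature-set cutoff from an elimination trace
#'
#' Computes the strictness cutoff from the per-step median AUROCs and maps
#' it to a feature set: scanning from the final (smallest) step backward,
#' the first step whose median AUROC meets the cutoff wins, maximizing
#' shrinkage subject to the AUROC bar.
#'
#' @param trace A [run_rfe()] result.
#' @param gamma Strictness in (0, 1); higher values lower the cutoff.
#' @return An object of class `sivs_cutoff`: `gamma`, `x_min`, `x_max`,
#'   `cutoff`, `selected_features`, `step_index`.
#' @export
suggest_cutoff <- function(trace, gamma = 0.01) {
  stopifnot(inherits(trace, "sivs_rfe_trace"))
  if (!(is.numeric(gamma) && length(gamma) == 1 && gamma > 0 && gamma < 1))
    sivs_stop("gamma must lie strictly in (0, 1)",
              class = "sivsel_parameter_error")
  med <- vapply(trace$steps, `[[`, numeric(1), "median_auroc")
  x_min <- min(med)
  x_max <- max(med)
  cutoff <- (1 - gamma) * (x_max - x_min) + x_min
  # smallest qualifying remaining set: scan from the final step backward
  qual <- which(med >= cutoff)
  step_index <- qual[length(qual)]
  sel <- trace$steps[[step_index]]$remaining_features
  structure(list(gamma = gamma, x_min = x_min, x_max = x_max,
                 cutoff = cutoff, selected_features = sel,
                 step_index = trace$steps[[step_index]]$step),
            class = "sivs_cutoff")
}

#' @export
print.sivs_cutoff <- function(x, ...) {
  cat("<cutoff suggestion> gamma =", x$gamma,
      "| AUROC cutoff =", signif(x$cutoff, 4),
      sprintf("(range %.4f-%.4f)", x$x_min, x$x_max),
      "|", length(x$selected_features), "features\n")
  invisible(x)
}

#' End-to-end stable feature selection
#'
#' Composes the full pipeline on a raw dataset: preprocessing, iterative
#' model building, VIMP scoring, recursive elimination, and the cutoff
#' suggestion. When fewer than two features attain positive VIMP the
#' elimination stage is skipped and the selection is that (possibly empty)
#' set, with a status of `"no_stable_features"` or `"single_feature"`.
#'
#' @param dataset A raw [sivs_dataset()].
#' @param config A [sivs_config()].
#' @return An object of class `sivs_result`; see [write_result()] for the
#'   serialized layout.
#' @export
select_features <- function(dataset, config = sivs_config()) {
  stopifnot(inherits(dataset, "sivs_dataset"))
  stage <- function(name, expr) {
    tryCatch(expr, sivsel_error = function(e) {
      e$message <- paste0("[", name, "] ", conditionMessage(e))
      stop(e)
    })
  }
  prep <- stage("preprocess", preprocess(dataset, config$on_missing))
  ens <- stage("iterations", run_iterations(prep$dataset, config))
  vimp <- stage("vimp", build_vimp_table(ens))
  positive <- vimp$feature[vimp$vimp > 0]
  if (length(positive) >= 2) {
    trace <- stage("rfe", run_rfe(prep$dataset, vimp, config))
    cutoff <- stage("cutoff", suggest_cutoff(trace, config$gamma))
    selected <- cutoff$selected_features
    status <- "ok"
  } else {
    trace <- NULL
    cutoff <- NULL
    selected <- positive
    status <- if (length(positive) == 0) "no_stable_features"
              else "single_feature"
  }
  structure(list(schema_version = SCHEMA_VERSION,
                 config = config,
                 preprocess_report = prep$report,
                 ensemble = ens,
                 vimp_table = vimp,
                 rfe_trace = trace,
                 cutoff = cutoff,
                 selected_features = selected,
                 status = status),
            class = "sivs_result")
}

#' @export
print.sivs_result <- function(x, ...) {
  cat("<sivs_result> status:", x$status, "\n")
  cat("  iterations:", x$config$iterations,
      "| positive-VIMP features:", sum(x$vimp_table$vimp > 0), "\n")
  cat("  selected (", length(x$selected_features), "): ",
      paste(utils::head(x$selected_features, 10), collapse = ", "),
      if (length(x$selected_features) > 10) ", ...", "\n", sep = "")
  if (!is.null(x$cutoff))
    cat("  AUROC cutoff:", signif(x$cutoff$cutoff, 4),
        "at gamma =", x$cutoff$gamma, "\n")
  invisible(x)
}
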