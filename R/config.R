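#' Run configuration
#'
#' Collects every tunable of the pipeline. Defaults follow common practice
#' for stable selection with a cross-validated L1 logistic learner:
#' 100 ensemble iterations, 100 elimination repeats, 10 folds, strictness
#' 0.01.
#'
#' @param iterations Number of ensemble model-building iterations, k >= 1.
#' @param rfe_repeats Models refit per elimination step, r >= 1.
#' @param cv_folds Cross-validation folds V >= 2.
#' @param gamma Strictness of the cutoff suggestion, in (0, 1); higher
#'   values lower the suggested AUROC bar and retain fewer features.
#' @param master_seed Integer master seed; all per-fit fold seeds derive
#'   from it.
#' @param positive_class Optional response level treated as positive;
#'   defaults to the second factor level.
#' @param alpha Elastic-net mixing parameter of the internal learner
#'   (1 = LASSO, the default).
#' @param rfe_auroc How per-step AUROC is computed: from full training-set
#'   predictions (`"train"`, default) or from out-of-fold predictions
#'   (`"out_of_fold"`, less optimistic).
#' @param on_missing Missing-value policy: drop incomplete samples
#'   (`"drop"`) or fail (`"error"`).
#' @param threads Worker count for per-fit parallelism; results are
#'   reduced in run order so outputs do not depend on scheduling.
#' @param verbose Emit per-stage progress messages.
#' @return An object of class `sivs_config`.
#' @export
sivs_config <- function(iterations = 100, rfe_repeats = 100, cv_folds = 10,
                        gamma = 0.01, master_seed = 1,
                        positive_class = NULL, alpha = 1,
                        rfe_auroc = c("train", "out_of_fold"),
                        on_missing = c("drop", "error"),
                        threads = 1, verbose = FALSE) {
  rfe_auroc <- match.arg(rfe_auroc)
  on_missing <- match.arg(on_missing)
  chk <- function(ok, what)
    if (!ok) sivs_stop("invalid config: ", what,
                       class = "sivsel_parameter_error")
  chk(iterations >= 1, "iterations must be >= 1")
  chk(rfe_repeats >= 1, "rfe_repeats must be >= 1")
  chk(cv_folds >= 2, "cv_folds must be >= 2")
  chk(gamma > 0 && gamma < 1, "gamma must lie strictly in (0, 1)")
  chk(threads >= 1, "threads must be >= 1")
  structure(list(iterations = as.integer(iterations),
                 rfe_repeats = as.integer(rfe_repeats),
                 cv_folds = as.integer(cv_folds),
                 gamma = gamma,
                 master_seed = as.integer(master_seed),
                 positive_class = positive_class,
                 alpha = alpha,
                 rfe_auroc = rfe_auroc,
                 on_missing = on_missing,
                 threads = as.integer(threads),
                 verbose = isTRUE(verbose)),
            class = "sivs_config")
}

#' Read a run configuration from a YAML or JSON file
#'
#' The file holds a flat mapping of [sivs_config()] argument names to
#' values; `overrides` (e.g. command-line flags) take precedence over file
#' values.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` for
#'   defaults only.
#' @param overrides Named list of values overriding the file.
#' @return A `sivs_config`.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path))
      sivs_stop("config file not found: ", path, class = "sivsel_io_error")
    vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    unknown <- setdiff(names(vals), names(formals(sivs_config)))
    if (length(unknown) > 0)
      sivs_stop("unknown config key(s): ", paste(unknown, collapse = ", "),
                class = "sivsel_parameter_error")
  }
  vals <- modifyList(vals, overrides[!vapply(overrides, is.null, logical(1))])
  do.call(sivs_config, vals)
}

config_message <- function(config, ...) {
  if (isTRUE(config$verbose)) message(...)
}

# Ordered map/lapply honouring config$threads; results come back in input
# order regardless of scheduling.
run_map <- function(config, xs, fn) {
  if ((config$threads %||% 1L) > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(xs, fn, mc.cores = config$threads,
                       mc.preschedule = TRUE)
  } else {
    lapply(xs, fn)
  }
}
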