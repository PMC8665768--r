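# Iterative model building and variable-importance (VIMP) scoring.
#
# k cross-validated L1 logistic fits are run under distinct fold seeds;
# the collected coefficient matrix is aggregated per feature into
#
#   vimp(f) = I(c*) * mabs(c*) * |c*| / (1 + IQR(c*))
#
# where c* are the feature's nonzero coefficients across runs, I is the
# sign-consistency indicator, mabs the median absolute value, |c*| the
# selection count and IQR the interquartile range (type-7 quantiles).

#' Build the coefficient ensemble by iterative model fitting
#'
#' Fits `config$iterations` models, each with a fold seed derived
#' deterministically from `config$master_seed`, and collects their
#' coefficient vectors and training AUROCs. A failing fit is recorded and
#' excluded with a warning; more than 10% failures abort.
#'
#' @param dataset A preprocessed (numeric, standardized) [sivs_dataset()].
#' @param config A [sivs_config()].
#' @return An object of class `sivs_ensemble`: `coef` (k_ok x p matrix,
#'   rows = successful runs), `meta` (data.frame `run`, `seed`, `penalty`,
#'   `train_auroc`, `ok`), `feature_names`.
#' @export
run_iterations <- function(dataset, config = sivs_config()) {
  stopifnot(inherits(dataset, "sivs_dataset"), inherits(config, "sivs_config"))
  X <- dataset_matrix(dataset)
  y <- dataset$y
  y01 <- response_binary(y, config$positive_class)
  k <- config$iterations
  seeds <- derive_seeds(config$master_seed, k, stream = "iterations")
  learner <- make_learner(config)
  config_message(config, "iterative model building: k = ", k)
  fits <- run_map(config, seq_len(k), function(j) {
    tryCatch(learner(X, y, seeds[j]),
             sivsel_contract_error = function(e) stop(e),
             error = function(e) structure(list(message = conditionMessage(e)),
                                           class = "sivs_fit_failure"))
  })
  ok <- !vapply(fits, inherits, logical(1), "sivs_fit_failure")
  if (any(!ok)) {
    warning(sum(!ok), " of ", k, " iterative fits failed and were excluded",
            call. = FALSE)
    if (mean(!ok) > 0.1)
      sivs_stop("more than 10% of iterative fits failed",
                class = "sivsel_data_error")
  }
  coefs <- do.call(rbind, lapply(fits[ok], `[[`, "coefficients"))
  colnames(coefs) <- colnames(X)
  meta <- data.frame(
    run = seq_len(k), seed = seeds,
    penalty = vapply(fits, function(f)
      if (inherits(f, "sivs_fit")) f$chosen_penalty else NA_real_, numeric(1)),
    train_auroc = vapply(fits, function(f)
      if (inherits(f, "sivs_fit")) auroc(y01, f$train_scores) else NA_real_,
      numeric(1)),
    ok = ok)
  structure(list(coef = coefs, meta = meta, feature_names = colnames(X)),
            class = "sivs_ensemble")
}

#' Selection frequency per feature
#'
#' Number of ensemble runs in which each feature had a nonzero
#' coefficient.
#'
#' @param ensemble A `sivs_ensemble`.
#' @return Named integer vector over features.
#' @export
selection_frequency <- function(ensemble) {
  stopifnot(inherits(ensemble, "sivs_ensemble"))
  colSums(abs(ensemble$coef) >= NONZERO_TOL)
}

#' Sign-consistency indicator
#'
#' 1 if all nonzero coefficients of a feature share one sign, else 0.
#'
#' @param nonzero_coefs Numeric vector of nonzero coefficient values,
#'   length >= 1.
#' @return 0 or 1.
#' @export
sign_consistency <- function(nonzero_coefs) {
  if (length(nonzero_coefs) == 0)
    sivs_stop("sign_consistency() requires a non-empty vector; the ",
              "never-selected case is handled by the caller",
              class = "sivsel_contract_error")
  if (all(nonzero_coefs > 0) || all(nonzero_coefs < 0)) 1 else 0
}

#' Variable-importance score of one feature
#'
#' For the vector `c*` of a feature's nonzero coefficients across runs:
#' sign-consistency indicator x median absolute value x count, divided by
#' one plus the interquartile range of `c*` (type-7 quantiles, the signed
#' values). A feature never selected (empty `c*`) scores 0.
#'
#' @param nonzero_coefs Numeric vector of nonzero coefficient values
#'   (possibly empty).
#' @return Non-negative scalar.
#' @export
vimp_score <- function(nonzero_coefs) {
  if (length(nonzero_coefs) == 0) return(0)
  ind <- sign_consistency(nonzero_coefs)
  if (ind == 0) return(0)
  mabs <- median(abs(nonzero_coefs))
  iqr <- unname(diff(quantile(nonzero_coefs, c(0.25, 0.75), type = 7)))
  ind * mabs * length(nonzero_coefs) / (1 + iqr)
}

#' Aggregate an ensemble into the per-feature VIMP table
#'
#' Applies [vimp_score()] to every feature's nonzero coefficients and
#' sorts by VIMP descending; ties break by higher selection count, then
#' lexicographic feature name, so the downstream elimination order is
#' deterministic.
#'
#' @param ensemble A `sivs_ensemble`.
#' @return A data.frame of class `sivs_vimp_table` with columns `feature`,
#'   `count`, `sign_consistent`, `mabs`, `iqr`, `median_coef`, `vimp`,
#'   plus attribute `n_runs` (successful runs) and `nonzero_coefs`
#'   (named list of each feature's nonzero coefficient vector, the data
#'   behind per-feature coefficient-distribution plots).
#' @export
build_vimp_table <- function(ensemble) {
  stopifnot(inherits(ensemble, "sivs_ensemble"))
  if (nrow(ensemble$coef) == 0)
    sivs_stop("empty ensemble", class = "sivsel_data_error")
  nz <- lapply(seq_along(ensemble$feature_names), function(i) {
    v <- ensemble$coef[, i]
    v[abs(v) >= NONZERO_TOL]
  })
  names(nz) <- ensemble$feature_names
  tab <- data.frame(
    feature = ensemble$feature_names,
    count = vapply(nz, length, integer(1)),
    sign_consistent = vapply(nz, function(v)
      if (length(v) == 0) 0 else sign_consistency(v), numeric(1)),
    mabs = vapply(nz, function(v)
      if (length(v) == 0) NA_real_ else median(abs(v)), numeric(1)),
    iqr = vapply(nz, function(v)
      if (length(v) == 0) NA_real_
      else unname(diff(quantile(v, c(0.25, 0.75), type = 7))), numeric(1)),
    median_coef = vapply(nz, function(v)
      if (length(v) == 0) NA_real_ else median(v), numeric(1)),
    vimp = vapply(nz, vimp_score, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(-tab$vimp, -tab$count, tab$feature)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, n_runs = nrow(ensemble$coef), nonzero_coefs = nz,
            class = c("sivs_vimp_table", "data.frame"))
}
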