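# The pluggable "internal method": a learner with cross-validation-dependent
# embedded feature selection. The default is an L1-penalized logistic
# regression whose penalty is chosen by V-fold cross-validation under a
# given fold seed; the zero pattern of its coefficients defines "selected".

#' Class-stratified cross-validation fold assignment
#'
#' Assigns every sample to one of `V` folds, stratified by class so that
#' within each class the fold sizes differ by at most one and every fold
#' contains both classes.
#'
#' @param labels Binary response (factor or vector with two distinct
#'   values).
#' @param V Number of folds, `>= 2`.
#' @param seed Integer seed; the assignment is deterministic in it.
#' @return An object of class `sivs_folds`: list with `fold` (integer
#'   vector in `1..V`), `V`, `seed`.
#' @export
assign_folds <- function(labels, V, seed) {
  labels <- as.factor(labels)
  if (V < 2) sivs_stop("V must be >= 2", class = "sivsel_parameter_error")
  tab <- table(labels)
  if (any(tab < V))
    sivs_stop("class '", names(tab)[which.min(tab)], "' has ", min(tab),
              " samples, fewer than V = ", V, "; reduce the fold count",
              class = "sivsel_data_error")
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      members <- which(labels == cl)
      fold[members] <- sample(rep(seq_len(V), length.out = length(members)))
    }
  })
  structure(list(fold = fold, V = as.integer(V), seed = as.integer(seed)),
            class = "sivs_folds")
}

# Penalty grid: 100 log-spaced values from the data-derived maximal penalty
# (the smallest penalty with an all-zero solution; for the logistic family
# on standardized columns this is max|x_j'(y - ybar)|/n) down to 1e-3 of it.
penalty_grid <- function(X, y01, n_penalties = 100, min_ratio = 1e-3) {
  n <- nrow(X)
  lmax <- max(abs(crossprod(X, y01 - mean(y01)))) / n
  if (lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_penalties))
}

#' Fit the default internal learner
#'
#' Fits the L1-penalized (alpha = 1) logistic regression path over a
#' log-spaced penalty grid and selects the penalty minimizing the mean
#' cross-validated binomial deviance over the supplied folds; the returned
#' coefficients are from the refit on all training data at that penalty.
#' Deterministic given `(X, y, folds, grid)`.
#'
#' With a single feature column the L1 path degenerates; an unpenalized
#' univariate logistic fit is used instead (`chosen_penalty = 0`).
#'
#' @param X Standardized numeric matrix (samples x features).
#' @param y Binary response (factor or 0/1).
#' @param folds A [assign_folds()] result valid for `y`.
#' @param penalty_grid Optional decreasing vector of penalties; defaults to
#'   the data-derived grid.
#' @param alpha Elastic-net mixing parameter; 1 (default) is pure LASSO.
#' @return An object of class `sivs_fit`: `coefficients` (named vector,
#'   no intercept), `intercept`, `chosen_penalty`, `cv_curve` (data.frame
#'   `penalty`, `deviance`), `train_scores` (probabilities in `[0,1]`),
#'   `oof_scores` (out-of-fold probabilities), `seed`.
#' @export
fit_internal <- function(X, y, folds, penalty_grid = NULL, alpha = 1) {
  stopifnot(inherits(folds, "sivs_folds"))
  X <- as.matrix(X)
  y01 <- if (is.factor(y)) response_binary(y) else as.integer(y)
  if (length(y01) != nrow(X))
    sivs_stop("X and y disagree on sample count", class = "sivsel_data_error")
  if (ncol(X) == 1L) return(fit_univariate(X, y01, folds))
  grid <- penalty_grid %||% penalty_grid(X, y01)
  # Convergence tolerance 1e-5: the selected penalty and the nonzero
  # pattern are insensitive to tightening it further, while path fitting
  # is several times faster.
  fit <- glmnet::cv.glmnet(X, y01, family = "binomial", alpha = alpha,
                           lambda = grid, foldid = folds$fold,
                           standardize = FALSE, type.measure = "deviance",
                           keep = TRUE, thresh = 1e-5)
  lam <- fit$lambda.min
  cf <- as.numeric(coef(fit, s = lam))
  names(cf) <- c("(Intercept)", colnames(X))
  scores <- as.numeric(predict(fit, newx = X, s = lam, type = "response"))
  oof <- plogis(fit$fit.preval[, which(fit$lambda == lam)])
  structure(list(coefficients = cf[-1L], intercept = cf[[1L]],
                 chosen_penalty = lam,
                 cv_curve = data.frame(penalty = fit$lambda,
                                       deviance = fit$cvm),
                 train_scores = scores, oof_scores = oof,
                 seed = folds$seed),
            class = "sivs_fit")
}

# Degenerate single-column case: unpenalized logistic fit; out-of-fold
# scores come from per-fold refits.
fit_univariate <- function(X, y01, folds) {
  df <- data.frame(y = y01, x = X[, 1L])
  m <- suppressWarnings(glm(y ~ x, family = binomial(), data = df))
  scores <- as.numeric(predict(m, type = "response"))
  oof <- rep(NA_real_, nrow(X))
  for (v in seq_len(folds$V)) {
    hold <- folds$fold == v
    mv <- suppressWarnings(glm(y ~ x, family = binomial(),
                               data = df[!hold, , drop = FALSE]))
    oof[hold] <- as.numeric(predict(mv, newdata = df[hold, , drop = FALSE],
                                    type = "response"))
  }
  structure(list(coefficients = setNames(coef(m)[["x"]], colnames(X)[1L]),
                 intercept = coef(m)[["(Intercept)"]],
                 chosen_penalty = 0,
                 cv_curve = data.frame(penalty = numeric(0),
                                       deviance = numeric(0)),
                 train_scores = scores, oof_scores = oof,
                 seed = folds$seed),
            class = "sivs_fit")
}

#' Names of the features a fit selected
#'
#' A feature is selected when its coefficient magnitude is at least the
#' package-wide nonzero threshold (1e-8).
#'
#' @param fit A `sivs_fit`.
#' @return Character vector of selected feature names.
#' @export
selected_features <- function(fit) {
  stopifnot(inherits(fit, "sivs_fit"))
  names(fit$coefficients)[abs(fit$coefficients) >= NONZERO_TOL]
}

# Learner contract: fit(X, y, fold_seed) -> sivs_fit whose coefficient
# vector is as long as ncol(X). Used by the ensemble and RFE stages; any
# learner satisfying it can replace the default.
make_learner <- function(config) {
  V <- config$cv_folds
  alpha <- config$alpha %||% 1
  function(X, y, fold_seed) {
    folds <- assign_folds(y, V, fold_seed)
    fit <- fit_internal(X, y, folds, alpha = alpha)
    check_learner_contract(fit, ncol(X))
    fit
  }
}

check_learner_contract <- function(fit, p) {
  if (!inherits(fit, "sivs_fit") || length(fit$coefficients) != p)
    sivs_stop("learner contract violation: expected a coefficient vector of ",
              "length ", p, ", got ",
              if (inherits(fit, "sivs_fit")) length(fit$coefficients)
              else class(fit)[1],
              class = "sivsel_contract_error")
  if (any(fit$train_scores < 0 | fit$train_scores > 1))
    sivs_stop("learner contract violation: train_scores outside [0, 1]",
              class = "sivsel_contract_error")
  invisible(fit)
}
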