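# General preprocessing: degeneracy filter, sample completeness, categorical
# encoding, standardization. The pipeline order is fixed; see preprocess().

#' Remove degenerate features
#'
#' Drops numeric columns whose variance is exactly zero and categorical
#' columns with a single observed level. "Zero variance" is tested exactly
#' (no epsilon): near-constant columns are retained and left to the
#' penalized fit.
#'
#' @param dataset A [sivs_dataset()].
#' @return A list with elements `dataset` and `removed` (a data.frame of
#'   `feature`, `reason` with reason one of `zero_variance`,
#'   `single_class`).
#' @export
drop_degenerate_features <- function(dataset) {
  stopifnot(inherits(dataset, "sivs_dataset"))
  reasons <- vapply(dataset$X, function(col) {
    if (is.numeric(col)) {
      v <- var(col, na.rm = TRUE)
      if (!is.na(v) && v == 0) "zero_variance" else NA_character_
    } else {
      if (length(unique(col[!is.na(col)])) <= 1L) "single_class"
      else NA_character_
    }
  }, character(1))
  removed <- data.frame(feature = names(reasons)[!is.na(reasons)],
                        reason = unname(reasons[!is.na(reasons)]),
                        stringsAsFactors = FALSE)
  keep <- names(reasons)[is.na(reasons)]
  if (length(keep) == 0L)
    sivs_stop("no usable features: every column is degenerate",
              class = "sivsel_data_error")
  list(dataset = dataset_subset(dataset, features = keep), removed = removed)
}

#' Remove samples with missing values
#'
#' @param dataset A [sivs_dataset()].
#' @return A list with elements `dataset` and `dropped_samples` (character
#'   vector of sample ids removed because of missing values).
#' @export
drop_incomplete_samples <- function(dataset) {
  stopifnot(inherits(dataset, "sivs_dataset"))
  incomplete <- rowSums(is.na(dataset$X)) > 0
  dropped <- dataset$sample_ids[incomplete]
  out <- dataset_subset(dataset, samples = which(!incomplete))
  if (nlevels(droplevels(out$y)) < 2L)
    sivs_stop("missing-value removal left fewer than two response classes",
              class = "sivsel_data_error")
  list(dataset = out, dropped_samples = dropped)
}

#' Encode categorical features as indicator columns
#'
#' Each categorical feature with L >= 2 observed levels becomes L - 1
#' indicator columns named `<feature>=<level>`; the reference level is the
#' first in lexicographic order. Numeric columns pass through unchanged.
#'
#' @param dataset A [sivs_dataset()] free of degenerate features.
#' @return A list with elements `dataset` (all-numeric) and `encoding`
#'   (named list: feature -> character vector of emitted column names).
#' @export
encode_categoricals <- function(dataset) {
  stopifnot(inherits(dataset, "sivs_dataset"))
  encoding <- list()
  cols <- list()
  for (nm in names(dataset$X)) {
    col <- dataset$X[[nm]]
    if (is.numeric(col)) {
      cols[[nm]] <- col
    } else {
      col <- factor(col, levels = sort(unique(as.character(col))))
      lv <- levels(col)
      emitted <- character(0)
      for (l in lv[-1L]) {
        new_nm <- paste0(nm, "=", l)
        cols[[new_nm]] <- as.numeric(col == l)
        emitted <- c(emitted, new_nm)
      }
      encoding[[nm]] <- emitted
    }
  }
  X <- as.data.frame(cols, check.names = FALSE, optional = TRUE)
  out <- structure(list(X = X, feature_names = names(X), y = dataset$y,
                        sample_ids = dataset$sample_ids,
                        truth = dataset$truth),
                   class = "sivs_dataset")
  list(dataset = out, encoding = encoding)
}

#' Standardize all columns to mean zero and unit standard deviation
#'
#' Uses the sample standard deviation (n - 1 denominator). Indicator
#' columns produced by [encode_categoricals()] are standardized like any
#' numeric column so that coefficients are on a common scale.
#'
#' @param dataset An all-numeric [sivs_dataset()].
#' @return A list with elements `dataset` and `scaling` (data.frame of
#'   `feature`, `mean`, `sd`).
#' @export
standardize <- function(dataset) {
  stopifnot(inherits(dataset, "sivs_dataset"))
  if (!all(vapply(dataset$X, is.numeric, logical(1))))
    sivs_stop("standardize() requires all-numeric columns; encode first",
              class = "sivsel_internal_error")
  mu <- vapply(dataset$X, mean, numeric(1))
  sdev <- vapply(dataset$X, sample_sd, numeric(1))
  if (any(sdev == 0))
    sivs_stop("zero-sd column reached standardization: ",
              paste(names(dataset$X)[sdev == 0], collapse = ", "),
              class = "sivsel_internal_error")
  X <- as.data.frame(Map(function(col, m, s) (col - m) / s,
                         dataset$X, mu, sdev),
                     check.names = FALSE, optional = TRUE)
  out <- structure(list(X = X, feature_names = names(X), y = dataset$y,
                        sample_ids = dataset$sample_ids,
                        truth = dataset$truth),
                   class = "sivs_dataset")
  list(dataset = out,
       scaling = data.frame(feature = names(dataset$X), mean = unname(mu),
                            sd = unname(sdev), stringsAsFactors = FALSE))
}

#' Run the full preprocessing pipeline
#'
#' Fixed order: degeneracy filter, sample-completeness filter, a second
#' degeneracy pass (sample removal can create new constant columns),
#' categorical encoding, standardization. The composed transform is
#' idempotent on its own output up to floating-point tolerance.
#'
#' @param dataset A raw [sivs_dataset()].
#' @param on_missing `"drop"` (default) removes samples with missing
#'   values; `"error"` fails instead.
#' @return A list with elements `dataset` (numeric, standardized) and
#'   `report` (class `sivs_preprocess_report`: `removed_features`,
#'   `dropped_samples`, `encoding`, `scaling`).
#' @export
preprocess <- function(dataset, on_missing = c("drop", "error")) {
  on_missing <- match.arg(on_missing)
  s1 <- drop_degenerate_features(dataset)
  if (on_missing == "error" && anyNA(s1$dataset$X))
    sivs_stop("input contains missing values (on_missing = 'error')",
              class = "sivsel_data_error")
  s2 <- drop_incomplete_samples(s1$dataset)
  s2b <- drop_degenerate_features(s2$dataset)
  removed <- rbind(s1$removed, s2b$removed)
  s3 <- encode_categoricals(s2b$dataset)
  s4 <- standardize(s3$dataset)
  report <- structure(list(removed_features = removed,
                           dropped_samples = s2$dropped_samples,
                           encoding = s3$encoding,
                           scaling = s4$scaling),
                      class = "sivs_preprocess_report")
  list(dataset = s4$dataset, report = report)
}

#' Apply a fitted preprocessing report to new data
#'
#' Re-applies the training-set preprocessing (feature removal, encoding
#' with the training levels, training means/sds) to a new dataset, e.g. a
#' validation set, so models can score it.
#'
#' @param dataset A raw [sivs_dataset()] sharing the training feature
#'   space.
#' @param report A `sivs_preprocess_report` from [preprocess()].
#' @return A numeric, standardized `sivs_dataset`.
#' @export
apply_preprocess <- function(dataset, report) {
  stopifnot(inherits(report, "sivs_preprocess_report"))
  keep <- setdiff(dataset$feature_names, report$removed_features$feature)
  d <- dataset_subset(dataset, features = keep)
  complete <- which(rowSums(is.na(d$X)) == 0)
  d <- dataset_subset(d, samples = complete)
  cols <- list()
  for (nm in names(d$X)) {
    col <- d$X[[nm]]
    if (!is.null(report$encoding[[nm]])) {
      col <- as.character(col)
      for (new_nm in report$encoding[[nm]]) {
        lev <- sub("^.*=", "", new_nm)
        cols[[new_nm]] <- as.numeric(col == lev)
      }
    } else {
      cols[[nm]] <- col
    }
  }
  X <- as.data.frame(cols, check.names = FALSE, optional = TRUE)
  sc <- report$scaling
  missing_cols <- setdiff(sc$feature, names(X))
  if (length(missing_cols) > 0)
    sivs_stop("new data lacks feature(s): ",
              paste(missing_cols, collapse = ", "),
              class = "sivsel_data_error")
  X <- X[, sc$feature, drop = FALSE]
  for (i in seq_len(nrow(sc)))
    X[[i]] <- (X[[i]] - sc$mean[i]) / sc$sd[i]
  structure(list(X = X, feature_names = names(X), y = d$y,
                 sample_ids = d$sample_ids, truth = d$truth),
            class = "sivs_dataset")
}

#' @export
print.sivs_preprocess_report <- function(x, ...) {
  cat("<preprocess report> removed features:", nrow(x$removed_features),
      "| dropped samples:", length(x$dropped_samples),
      "| encoded categoricals:", length(x$encoding),
      "| scaled columns:", nrow(x$scaling), "\n")
  invisible(x)
}
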