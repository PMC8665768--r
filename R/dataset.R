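#' Construct a modeling dataset
#'
#' The container consumed by every stage of the pipeline: a feature table
#' (numeric and/or factor columns), a binary response, and sample
#' identifiers. For synthetic data the names of the truly informative
#' features can be attached for downstream recovery checks.
#'
#' @param X A data.frame (samples in rows, features in columns). Numeric
#'   columns are treated as continuous, character/factor columns as
#'   categorical.
#' @param y Binary response: a vector coercible to a factor with exactly
#'   two levels.
#' @param sample_ids Unique sample identifiers; defaults to row names or
#'   `sample_1..n`.
#' @param truth Optional character vector naming the truly informative
#'   features (synthetic data only).
#' @return An object of class `sivs_dataset` with elements `X`,
#'   `feature_names`, `y`, `sample_ids`, `truth`.
#' @export
sivs_dataset <- function(X, y, sample_ids = NULL, truth = NULL) {
  X <- as.data.frame(X, stringsAsFactors = FALSE)
  if (anyDuplicated(names(X)))
    sivs_stop("duplicated feature name(s): ",
              paste(unique(names(X)[duplicated(names(X))]), collapse = ", "),
              class = "sivsel_format_error")
  if (any(!nzchar(names(X))))
    sivs_stop("feature names must be non-empty", class = "sivsel_format_error")
  if (length(y) != nrow(X))
    sivs_stop("length(y) (", length(y), ") != number of samples (", nrow(X), ")",
              class = "sivsel_data_error")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(X) %||% paste0("sample_", seq_len(nrow(X)))
    if (is.null(rownames(X))) sample_ids <- paste0("sample_", seq_len(nrow(X)))
  }
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    sivs_stop("duplicated sample id(s)", class = "sivsel_format_error")
  y <- droplevels(as.factor(y))
  if (any(is.na(y)))
    sivs_stop("response contains missing values", class = "sivsel_data_error")
  if (nlevels(y) != 2L)
    sivs_stop("response must have exactly two classes, found ", nlevels(y),
              class = "sivsel_data_error")
  # factors get a stable (sorted) level order
  X[] <- lapply(X, function(col) {
    if (is.character(col)) factor(col, levels = sort(unique(col))) else col
  })
  rownames(X) <- NULL
  structure(list(X = X,
                 feature_names = names(X),
                 y = y,
                 sample_ids = sample_ids,
                 truth = if (!is.null(truth)) as.character(truth)),
            class = "sivs_dataset")
}

#' @export
print.sivs_dataset <- function(x, ...) {
  cat("<sivs_dataset> ", nrow(x$X), " samples x ", ncol(x$X), " features; ",
      "classes: ", paste(levels(x$y), table(x$y), sep = "=", collapse = ", "),
      if (!is.null(x$truth)) paste0("; ", length(x$truth), " informative"),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.sivs_dataset <- function(x) dim(x$X)

# Subset a dataset by sample index and/or feature names.
dataset_subset <- function(dataset, samples = NULL, features = NULL) {
  X <- dataset$X
  ids <- dataset$sample_ids
  y <- dataset$y
  if (!is.null(samples)) {
    X <- X[samples, , drop = FALSE]
    ids <- ids[samples]
    y <- y[samples]
  }
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  rownames(X) <- NULL
  structure(list(X = X, feature_names = names(X), y = droplevels(y),
                 sample_ids = ids, truth = dataset$truth),
            class = "sivs_dataset")
}

# Numeric design matrix for a fully numeric dataset.
dataset_matrix <- function(dataset) {
  if (!all(vapply(dataset$X, is.numeric, logical(1))))
    sivs_stop("dataset still contains categorical columns; encode first",
              class = "sivsel_internal_error")
  m <- as.matrix(dataset$X)
  rownames(m) <- dataset$sample_ids
  m
}

# 0/1 response with the positive class as 1. The positive class defaults to
# the second factor level.
response_binary <- function(y, positive_class = NULL) {
  lv <- levels(y)
  pos <- positive_class %||% lv[2L]
  if (!pos %in% lv)
    sivs_stop("positive_class '", pos, "' is not a response level",
              class = "sivsel_parameter_error")
  as.integer(y == pos)
}
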