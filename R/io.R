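# External formats: CSV/TSV feature tables (samples in rows, features in
# columns), JSON result objects, JSON sidecars for synthetic data.

delim_for <- function(path) {
  if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a feature table with a binary response
#'
#' Reads a CSV (or, by extension `.tsv`/`.tab`/`.txt`, tab-separated)
#' table with samples in rows and a header of feature names. The response
#' is either an embedded column (named by `response`) or a separate
#' plain-text file with one label per line. A `sample_id` column, when
#' present, supplies sample identifiers. Empty cells and `NA` are read as
#' missing and surfaced to preprocessing, not imputed. Non-numeric columns
#' are treated as categorical.
#'
#' @param path Path to the table.
#' @param response Response column name (default `"response"`) or the path
#'   of a one-label-per-line file.
#' @return A [sivs_dataset()].
#' @export
read_feature_table <- function(path, response = "response") {
  if (!file.exists(path))
    sivs_stop("input file not found: ", path, class = "sivsel_io_error")
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"), quote = "\"",
                          comment.char = "")
  if (anyDuplicated(names(df)))
    sivs_stop("duplicated column name(s) in header: ",
              paste(unique(names(df)[duplicated(names(df))]), collapse = ", "),
              class = "sivsel_format_error")
  ids <- NULL
  if ("sample_id" %in% names(df)) {
    ids <- as.character(df[["sample_id"]])
    df[["sample_id"]] <- NULL
  }
  if (file.exists(response) && !response %in% names(df)) {
    y <- readLines(response)
    y <- y[nzchar(y)]
    if (length(y) != nrow(df))
      sivs_stop("response file has ", length(y), " labels for ", nrow(df),
                " samples", class = "sivsel_format_error")
  } else {
    if (!response %in% names(df))
      sivs_stop("response column '", response, "' not found in ", path,
                class = "sivsel_format_error")
    y <- df[[response]]
    df[[response]] <- NULL
  }
  sivs_dataset(df, y, sample_ids = ids)
}

#' Write a dataset as CSV (plus optional synthetic-truth sidecar)
#'
#' Samples in rows; feature columns under their names, the response in a
#' `response` column and ids in `sample_id`. When the dataset carries a
#' truth set (synthetic data), a sidecar JSON `<path>.meta.json` records
#' it together with the generating spec, if supplied.
#'
#' @param dataset A [sivs_dataset()].
#' @param path Output path (`.csv` or `.tsv`).
#' @param spec Optional [synthetic_spec()] recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, spec = NULL) {
  stopifnot(inherits(dataset, "sivs_dataset"))
  df <- cbind(data.frame(sample_id = dataset$sample_ids,
                         stringsAsFactors = FALSE),
              dataset$X,
              data.frame(response = as.character(dataset$y),
                         stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = delim_for(path), row.names = FALSE,
                     quote = FALSE)
  if (!is.null(dataset$truth) || !is.null(spec)) {
    meta <- list(truth = as.list(dataset$truth %||% character(0)),
                 spec = if (!is.null(spec)) unclass(spec),
                 seed = spec$seed)
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}

# ---- result (de)serialization -------------------------------------------

# Data frames are serialized column-wise so that vectors, not row
# records, come back from the reader.
df_to_cols <- function(df) lapply(as.list(df), function(col) I(col))

result_to_plain <- function(result) {
  ens <- result$ensemble
  nz <- which(ens$coef != 0, arr.ind = TRUE)
  list(
    schema_version = result$schema_version,
    status = result$status,
    config = unclass(result$config),
    preprocess_report = list(
      removed_features = df_to_cols(result$preprocess_report$removed_features),
      dropped_samples = as.list(result$preprocess_report$dropped_samples),
      encoding = result$preprocess_report$encoding,
      scaling = df_to_cols(result$preprocess_report$scaling)),
    ensemble = list(
      feature_names = as.list(ens$feature_names),
      n_runs_ok = nrow(ens$coef),
      coef_sparse = list(run = as.integer(nz[, 1]),
                         feature = as.integer(nz[, 2]),
                         value = as.numeric(ens$coef[nz])),
      meta = df_to_cols(ens$meta)),
    vimp_table = df_to_cols(as.data.frame(result$vimp_table)),
    rfe_trace = if (!is.null(result$rfe_trace)) list(
      elimination_order = as.list(result$rfe_trace$elimination_order),
      steps = lapply(result$rfe_trace$steps, function(s)
        list(step = s$step, removed_feature = s$removed_feature,
             remaining_features = as.list(s$remaining_features),
             auroc_samples = as.numeric(s$auroc_samples),
             median_auroc = s$median_auroc))),
    cutoff = if (!is.null(result$cutoff)) list(
      gamma = result$cutoff$gamma, x_min = result$cutoff$x_min,
      x_max = result$cutoff$x_max, cutoff = result$cutoff$cutoff,
      selected_features = as.list(result$cutoff$selected_features),
      step_index = result$cutoff$step_index),
    selected_features = as.list(result$selected_features))
}

plain_to_result <- function(pl) {
  cfg_fields <- pl$config
  cfg_fields <- cfg_fields[!vapply(cfg_fields, is.null, logical(1))]
  config <- do.call(sivs_config, cfg_fields)
  chr <- function(x) as.character(unlist(x) %||% character(0))
  feats <- chr(pl$ensemble$feature_names)
  k_ok <- pl$ensemble$n_runs_ok
  coef <- matrix(0, k_ok, length(feats), dimnames = list(NULL, feats))
  sp <- pl$ensemble$coef_sparse
  if (length(sp$run) > 0)
    coef[cbind(as.integer(sp$run), as.integer(sp$feature))] <-
      as.numeric(sp$value)
  m <- pl$ensemble$meta
  meta <- data.frame(run = as.integer(unlist(m$run)),
                     seed = as.integer(unlist(m$seed)),
                     penalty = as.numeric(unlist(m$penalty)),
                     train_auroc = as.numeric(unlist(m$train_auroc)),
                     ok = as.logical(unlist(m$ok)))
  ensemble <- structure(list(coef = coef, meta = meta,
                             feature_names = feats),
                        class = "sivs_ensemble")
  vimp <- build_vimp_table(ensemble)
  rf <- pl$preprocess_report$removed_features
  sc <- pl$preprocess_report$scaling
  report <- structure(list(
    removed_features = data.frame(feature = chr(rf$feature),
                                  reason = chr(rf$reason)),
    dropped_samples = chr(pl$preprocess_report$dropped_samples),
    encoding = lapply(pl$preprocess_report$encoding, chr),
    scaling = data.frame(feature = chr(sc$feature),
                         mean = as.numeric(unlist(sc$mean)),
                         sd = as.numeric(unlist(sc$sd)))),
    class = "sivs_preprocess_report")
  trace <- NULL
  if (!is.null(pl$rfe_trace)) {
    steps <- lapply(seq_along(pl$rfe_trace$steps), function(i) {
      s <- pl$rfe_trace$steps[[i]]
      list(step = as.integer(s$step),
           removed_feature = if (is.null(s$removed_feature)) NA_character_
                             else as.character(s$removed_feature),
           remaining_features = chr(s$remaining_features),
           auroc_samples = as.numeric(unlist(s$auroc_samples)),
           median_auroc = as.numeric(s$median_auroc))
    })
    trace <- structure(list(steps = steps,
                            elimination_order =
                              chr(pl$rfe_trace$elimination_order)),
                       class = "sivs_rfe_trace")
  }
  cutoff <- NULL
  if (!is.null(pl$cutoff)) {
    cutoff <- structure(list(gamma = pl$cutoff$gamma,
                             x_min = pl$cutoff$x_min,
                             x_max = pl$cutoff$x_max,
                             cutoff = pl$cutoff$cutoff,
                             selected_features = chr(pl$cutoff$selected_features),
                             step_index = as.integer(pl$cutoff$step_index)),
                        class = "sivs_cutoff")
  }
  structure(list(schema_version = pl$schema_version,
                 config = config,
                 preprocess_report = report,
                 ensemble = ensemble,
                 vimp_table = vimp,
                 rfe_trace = trace,
                 cutoff = cutoff,
                 selected_features = chr(pl$selected_features),
                 status = pl$status),
            class = "sivs_result")
}

#' Serialize a result to JSON
#'
#' The document carries a schema version; numeric values are written at
#' full double precision so [read_result()] restores the object
#' field-for-field.
#'
#' @param result A `sivs_result` from [select_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "sivs_result"))
  ok <- tryCatch({
    jsonlite::write_json(result_to_plain(result), path,
                         auto_unbox = TRUE, digits = I(17),
                         null = "null", na = "null", pretty = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    sivs_stop("cannot write result to '", path, "': ",
              conditionMessage(ok), class = "sivsel_io_error")
  invisible(path)
}

#' Read a serialized result
#'
#' @param path Path to a JSON file written by [write_result()].
#' @return A `sivs_result`.
#' @export
read_result <- function(path) {
  if (!file.exists(path))
    sivs_stop("result file not found: ", path, class = "sivsel_io_error")
  pl <- jsonlite::read_json(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  if (!identical(pl$schema_version, SCHEMA_VERSION))
    sivs_stop("result schema version '",
              pl$schema_version %||% "<missing>",
              "' does not match supported version '", SCHEMA_VERSION, "'",
              class = "sivsel_version_error")
  plain_to_result(pl)
}
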