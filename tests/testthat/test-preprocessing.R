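make_mixed <- function() {
  sivs_dataset(
    data.frame(num = c(1.5, 2.5, 3.5, 4.5),
               const = c(1, 1, 1, 1),
               near_const = c(1, 1 + 1e-12, 1, 1),
               cat3 = c("a", "b", "c", "b"),
               cat1 = c("M", "M", "M", "M"),
               stringsAsFactors = FALSE),
    y = c("neg", "pos", "neg", "pos"))
}

test_that("degenerate features are removed with the right reasons", {
  out <- drop_degenerate_features(make_mixed())
  expect_setequal(out$removed$feature, c("const", "cat1"))
  expect_equal(out$removed$reason[out$removed$feature == "const"],
               "zero_variance")
  expect_equal(out$removed$reason[out$removed$feature == "cat1"],
               "single_class")
  # zero variance means exactly zero: a 1e-12 wiggle survives
  expect_true("near_const" %in% out$dataset$feature_names)
})

test_that("an all-degenerate table is a data error", {
  d <- sivs_dataset(data.frame(a = c(1, 1), b = c("x", "x")),
                    y = c("A", "B"))
  expect_error(drop_degenerate_features(d), "no usable features")
})

test_that("categorical encoding emits L-1 reference-coded indicators", {
  d <- sivs_dataset(data.frame(f = c("a", "b", "c", "b"),
                               g = c("x", "y", "x", "y"),
                               z = c(1, 2, 3, 4)),
                    y = c("A", "B", "A", "B"))
  out <- encode_categoricals(d)
  expect_setequal(names(out$dataset$X), c("f=b", "f=c", "g=y", "z"))
  expect_equal(out$dataset$X[["f=b"]], c(0, 1, 0, 1))
  expect_equal(out$dataset$X[["f=c"]], c(0, 0, 1, 0))
  expect_equal(out$encoding, list(f = c("f=b", "f=c"), g = "g=y"))

  numeric_only <- sivs_dataset(data.frame(z = c(1, 2, 3)),
                               y = c("A", "B", "A"))
  out2 <- encode_categoricals(numeric_only)
  expect_identical(out2$dataset$X, numeric_only$X)
  expect_length(out2$encoding, 0)
})

test_that("standardization matches hand-computed values and is idempotent", {
  d <- sivs_dataset(data.frame(a = c(1, 2, 3), b = c(10, 20, 30)),
                    y = c("A", "B", "A"))
  out <- standardize(d)
  expect_equal(out$dataset$X$a, c(-1, 0, 1))
  expect_equal(out$scaling$mean, c(2, 20))
  expect_equal(out$scaling$sd, c(1, 10))

  two <- sivs_dataset(data.frame(a = c(10, 20)), y = c("A", "B"))
  expect_equal(standardize(two)$dataset$X$a,
               c(-1, 1) / sqrt(2), tolerance = 1e-12)

  again <- standardize(out$dataset)
  expect_equal(as.matrix(again$dataset$X), as.matrix(out$dataset$X),
               tolerance = 1e-12)
})

test_that("samples with missing values are dropped and reported", {
  d <- sivs_dataset(data.frame(a = c(1, NA, 3, 4), b = c(5, 6, 7, 8)),
                    y = c("A", "B", "A", "B"),
                    sample_ids = c("s1", "s2", "s3", "s4"))
  out <- drop_incomplete_samples(d)
  expect_equal(out$dropped_samples, "s2")
  expect_equal(out$dataset$sample_ids, c("s1", "s3", "s4"))

  clean <- drop_incomplete_samples(out$dataset)
  expect_length(clean$dropped_samples, 0)
  expect_identical(clean$dataset, out$dataset)

  one_class_gone <- sivs_dataset(data.frame(a = c(NA, NA, 3, 4)),
                                 y = c("A", "A", "B", "B"))
  expect_error(drop_incomplete_samples(one_class_gone), "classes")
})

test_that("full pipeline yields centred unit-variance columns and a report", {
  d <- generate_dataset(synthetic_spec(n_train = 60, p = 15,
                                       n_informative = 3,
                                       categorical_fraction = 0.2, seed = 8))
  d$X$dead <- 1
  d$X[5, 1] <- NA
  out <- preprocess(d)
  X <- as.matrix(out$dataset$X)
  expect_true(all(abs(colMeans(X)) < 1e-10))
  expect_true(all(abs(apply(X, 2, sd) - 1) < 1e-10))
  expect_true("dead" %in% out$report$removed_features$feature)
  expect_equal(out$report$dropped_samples, "sample_00005")
  expect_equal(nrow(out$report$scaling), ncol(X))

  # composed transform is idempotent on its own output
  again <- preprocess(out$dataset)
  expect_equal(as.matrix(again$dataset$X), X, tolerance = 1e-10)

  # indicator columns are standardized too
  enc_cols <- unlist(out$report$encoding)
  expect_true(all(enc_cols %in% colnames(X)))

  expect_error(preprocess(d, on_missing = "error"), "missing")
})

test_that("apply_preprocess reuses training encoding and scaling", {
  d <- generate_dataset(synthetic_spec(n_train = 80, p = 10,
                                       n_informative = 2,
                                       categorical_fraction = 0.3, seed = 2))
  parts <- split_train_valid(d, 30, seed = 2)
  pp <- preprocess(parts$train)
  v <- apply_preprocess(parts$valid, pp$report)
  expect_identical(colnames(v$X), pp$report$scaling$feature)
  # training stats, not validation stats: columns need not be centred,
  # but back-transforming must recover the raw values
  raw_first <- parts$valid$X[[1]]
  sc <- pp$report$scaling
  j <- match(names(parts$valid$X)[1], sc$feature)
  expect_equal(v$X[[sc$feature[j]]] * sc$sd[j] + sc$mean[j], raw_first)
})
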