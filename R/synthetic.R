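#' Specification of a synthetic binary-classification dataset
#'
#' Defines a reproducible generator with a sparse set of truly informative
#' features and block-equicorrelated noise. Two regimes are covered by one
#' generator: an omics-like high-dimensional regime
#' (`categorical_fraction = 0`, p >> n) and a clinical-like low-dimensional
#' regime with mixed categorical/numeric columns
#' (`categorical_fraction > 0`).
#'
#' @param n_train Positive number of training samples.
#' @param n_valid Non-negative number of validation samples (generated from
#'   the same model; use [split_train_valid()] to partition, or request
#'   them here and split by the `partition` attribute).
#' @param p Positive number of features.
#' @param n_informative Number of truly informative features, in `[0, p]`.
#' @param effect_size Absolute coefficient of each informative feature on
#'   the logit scale (signs alternate).
#' @param correlation Within-block equicorrelation of the noise features,
#'   in `[0, 1)`.
#' @param block_size Size of each correlated noise block, `<= p`; the
#'   default is `min(10, p)`.
#' @param intercept Intercept on the logit scale; 0 gives balanced classes
#'   in expectation.
#' @param categorical_fraction Fraction of features emitted as 3-level
#'   categoricals (tertile-binned latent Gaussians), in `[0, 1]`.
#' @param seed Integer seed; the same spec and seed reproduce the dataset
#'   exactly.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_train = 200, n_valid = 0, p = 100,
                           n_informative = 5, effect_size = 1.5,
                           correlation = 0.3, block_size = NULL,
                           intercept = 0, categorical_fraction = 0,
                           seed = 1) {
  chk <- function(ok, what) {
    if (!ok) sivs_stop("invalid synthetic spec: ", what,
                       class = "sivsel_parameter_error")
  }
  block_size <- block_size %||% min(10, p)
  chk(n_train >= 1, "n_train must be >= 1")
  chk(n_valid >= 0, "n_valid must be >= 0")
  chk(p >= 1, "p must be >= 1")
  chk(n_informative >= 0 && n_informative <= p,
      "n_informative must lie in [0, p]")
  chk(effect_size > 0, "effect_size must be > 0")
  chk(correlation >= 0 && correlation < 1, "correlation must lie in [0, 1)")
  chk(block_size >= 1 && block_size <= p, "block_size must lie in [1, p]")
  chk(categorical_fraction >= 0 && categorical_fraction <= 1,
      "categorical_fraction must lie in [0, 1]")
  structure(list(n_train = as.integer(n_train), n_valid = as.integer(n_valid),
                 p = as.integer(p), n_informative = as.integer(n_informative),
                 effect_size = effect_size, correlation = correlation,
                 block_size = as.integer(block_size), intercept = intercept,
                 categorical_fraction = categorical_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic dataset with known informative features
#'
#' Informative features are drawn independently (identity covariance) so
#' that ground-truth recovery is well-posed; noise features are drawn in
#' equicorrelated blocks to exercise the collinearity sensitivity of
#' L1-penalized fits. The true coefficient vector has `n_informative`
#' entries of magnitude `effect_size` with alternating signs and zeros
#' elsewhere; labels are Bernoulli(sigmoid(X beta + intercept)). If
#' `categorical_fraction > 0`, the last columns are tertile-binned into
#' 3-level categoricals after label generation.
#'
#' @param spec A [synthetic_spec()].
#' @return A [sivs_dataset()] of `n_train + n_valid` samples whose `truth`
#'   element names the informative features.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_train + spec$n_valid
  p <- spec$p
  with_seed(spec$seed, {
    X <- matrix(0, n, p)
    ninf <- spec$n_informative
    if (ninf > 0) X[, seq_len(ninf)] <- rnorm(n * ninf)
    nn <- p - ninf
    if (nn > 0) {
      noise <- matrix(rnorm(n * nn), n, nn)
      rho <- spec$correlation
      if (rho > 0) {
        blocks <- split(seq_len(nn),
                        ceiling(seq_len(nn) / spec$block_size))
        for (b in blocks) {
          z <- rnorm(n)
          noise[, b] <- sqrt(rho) * z + sqrt(1 - rho) * noise[, b]
        }
      }
      X[, ninf + seq_len(nn)] <- noise
    }
    beta <- numeric(p)
    if (ninf > 0)
      beta[seq_len(ninf)] <- spec$effect_size * (-1)^(seq_len(ninf) - 1)
    eta <- drop(X %*% beta) + spec$intercept
    yb <- rbinom(n, 1L, plogis(eta))
    nm <- sprintf("feat_%04d", seq_len(p))
    colnames(X) <- nm
    Xdf <- as.data.frame(X)
    ncat <- floor(spec$categorical_fraction * p)
    if (ncat > 0) {
      cat_cols <- seq.int(p - ncat + 1L, p)
      for (j in cat_cols) {
        qs <- quantile(X[, j], c(1, 2) / 3, names = FALSE)
        Xdf[[j]] <- cut(X[, j], breaks = c(-Inf, qs, Inf),
                        labels = c("low", "mid", "high"))
      }
    }
    y <- factor(ifelse(yb == 1L, "case", "control"),
                levels = c("control", "case"))
    sivs_dataset(Xdf, y,
                 sample_ids = sprintf("sample_%05d", seq_len(n)),
                 truth = if (ninf > 0) nm[seq_len(ninf)] else character(0))
  })
}

#' Stratified train/validation split
#'
#' Partitions a dataset into disjoint training and validation sets,
#' stratified by class so both partitions keep both classes. Per-class
#' validation counts are apportioned proportionally (largest remainder).
#'
#' @param dataset A [sivs_dataset()].
#' @param n_valid Number of validation samples, `< n`.
#' @param seed Integer seed controlling the random draw.
#' @return A list with elements `train` and `valid`, both `sivs_dataset`s.
#' @export
split_train_valid <- function(dataset, n_valid, seed = 1) {
  stopifnot(inherits(dataset, "sivs_dataset"))
  n <- nrow(dataset$X)
  if (n_valid >= n)
    sivs_stop("n_valid (", n_valid, ") must be < n (", n, ")",
              class = "sivsel_parameter_error")
  if (n_valid == 0) {
    return(list(train = dataset,
                valid = dataset_subset(dataset, samples = integer(0))))
  }
  tab <- table(dataset$y)
  # proportional allocation, largest remainder
  exact <- n_valid * as.numeric(tab) / n
  take <- floor(exact)
  rem <- n_valid - sum(take)
  if (rem > 0) {
    ord <- order(exact - take, decreasing = TRUE)
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
  }
  names(take) <- names(tab)
  if (any(as.numeric(tab) - take < 1))
    sivs_stop("n_valid too large: a class would vanish from the training set",
              class = "sivsel_data_error")
  if (any(take < 1))
    sivs_stop("n_valid too small to place both classes in the validation set",
              class = "sivsel_data_error")
  valid_idx <- with_seed(seed, {
    unlist(lapply(names(tab), function(cl) {
      members <- which(dataset$y == cl)
      sort(sample(members, take[[cl]]))
    }), use.names = FALSE)
  })
  valid_idx <- sort(valid_idx)
  list(train = dataset_subset(dataset, samples = setdiff(seq_len(n), valid_idx)),
       valid = dataset_subset(dataset, samples = valid_idx))
}
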