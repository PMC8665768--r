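# Internal helpers: scoped RNG and deterministic seed streams.

# Evaluate `code` under a temporary RNG state seeded with `seed`;
# the caller's RNG state is restored afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a reproducible stream of fit seeds from a master seed
#'
#' Every source of randomness in the package (fold assignment, synthetic
#' data, recursive elimination repeats) draws its seed from a named stream
#' so that runs are reproducible and streams do not collide.
#'
#' @param master_seed Integer master seed.
#' @param n Number of seeds to derive.
#' @param stream Character label separating independent uses
#'   (e.g. `"iterations"`, `"rfe"`).
#' @return Integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master_seed, n, stream = "default") {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            n >= 0)
  if (n == 0L) return(integer(0))
  # Fold the stream label into the seed so streams are independent.
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  base <- (abs(as.integer(master_seed)) + h) %% .Machine$integer.max
  with_seed(base, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sivs_stop <- function(..., class) {
  stop(structure(class = c(class, "sivsel_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

sample_sd <- function(x) stats::sd(x)
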