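# Evaluation statistics: AUROC (Mann-Whitney), the paired DeLong test for
# correlated AUROCs, the paired Wilcoxon signed-rank test, and
# selection-stability summaries.

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the fraction of (positive, negative) pairs
#' where the positive sample scores higher, ties counted 1/2. Computed
#' from midranks in O(n log n).
#'
#' @param labels Binary labels: 0/1, logical, or a two-level factor whose
#'   second level is positive.
#' @param scores Numeric scores, same length.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  y <- as_binary_labels(labels)
  if (length(y) != length(scores))
    sivs_stop("labels and scores differ in length", class = "sivsel_data_error")
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0 || n_neg == 0)
    sivs_stop("AUROC requires both classes present", class = "sivsel_data_error")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) != 2)
      sivs_stop("labels must have exactly two classes",
                class = "sivsel_data_error")
    return(as.integer(labels) - 1L)
  }
  u <- sort(unique(labels))
  if (length(u) == 1)
    sivs_stop("labels must have exactly two classes",
              class = "sivsel_data_error")
  if (length(u) != 2 || !all(u %in% c(0, 1)))
    sivs_stop("labels must be 0/1, logical, or a two-level factor",
              class = "sivsel_data_error")
  as.integer(labels)
}

# DeLong structural components (placement values): for each positive, the
# fraction of negatives it beats (ties 1/2), and vice versa. Midrank-based.
delong_placements <- function(y, scores) {
  pos <- scores[y == 1L]
  neg <- scores[y == 0L]
  m <- length(pos)
  n <- length(neg)
  all_r <- rank(c(pos, neg), ties.method = "average")
  v10 <- (all_r[seq_len(m)] - rank(pos, ties.method = "average")) / n
  v01 <- 1 - (all_r[m + seq_len(n)] - rank(neg, ties.method = "average")) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Paired DeLong test for two correlated AUROCs
#'
#' Compares the AUROCs of two score vectors evaluated on the same samples
#' using the DeLong variance of the AUROC difference (structural
#' components / placement values), with a two-sided normal p-value. When
#' the difference has zero estimated variance the p-value is 1 for equal
#' AUROCs and 0 otherwise.
#'
#' @param labels Binary labels shared by both score vectors.
#' @param scores_a,scores_b Numeric score vectors on the same samples.
#' @return A list: `auroc_a`, `auroc_b`, `z`, `p`.
#' @export
delong_paired_test <- function(labels, scores_a, scores_b) {
  y <- as_binary_labels(labels)
  if (length(scores_a) != length(y) || length(scores_b) != length(y))
    sivs_stop("scores must match labels in length", class = "sivsel_data_error")
  if (sum(y == 1L) == 0 || sum(y == 0L) == 0)
    sivs_stop("both classes must be present", class = "sivsel_data_error")
  pa <- delong_placements(y, scores_a)
  pb <- delong_placements(y, scores_b)
  m <- length(pa$v10)
  n <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  if (!is.finite(var_diff) || var_diff <= 0) {
    z <- if (d == 0) 0 else sign(d) * Inf
    p <- if (d == 0) 1 else 0
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  list(auroc_a = pa$auc, auroc_b = pb$auc, z = z, p = p)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on the paired differences `x - y`. Zero differences are
#' dropped before ranking (classic convention) and ties receive midranks.
#' The null distribution is exact for up to 25 nonzero differences
#' (enumerated by convolution over the realized rank multiset, so ties are
#' handled exactly); beyond that a normal approximation with tie
#' correction is used, without continuity correction. All differences zero
#' degenerates to p = 1 with a warning.
#'
#' @param x,y Equal-length numeric vectors of paired observations.
#' @return A list: `statistic` (sum of ranks of positive differences),
#'   `p`, `method`.
#' @export
paired_wilcoxon <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1)
    sivs_stop("x and y must be equal-length, non-empty",
              class = "sivsel_parameter_error")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; returning p = 1", call. = FALSE)
    return(list(statistic = 0, p = 1, method = "degenerate"))
  }
  r <- rank(abs(d), ties.method = "average")
  w <- sum(r[d > 0])
  if (n <= 25) {
    p <- signed_rank_exact_p(w, r)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    p <- 2 * pnorm(-abs(w - mu) / sqrt(sigma2))
    method <- "normal_approximation"
  }
  list(statistic = w, p = min(1, p), method = method)
}

# Exact two-sided p for the signed-rank statistic given the realized rank
# vector (midranks allowed): the null distribution of W+ over the 2^n
# equiprobable sign assignments is built by convolution on doubled ranks.
signed_rank_exact_p <- function(w, ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  dist <- numeric(total + 1L)  # dist[s + 1] = P(2 * W+ = s)
  dist[1L] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), dist[seq_len(total + 1L - ri)])
    dist <- (dist + shifted) / 2
  }
  w2 <- as.integer(round(2 * w))
  p_le <- sum(dist[seq_len(w2 + 1L)])
  p_ge <- sum(dist[seq.int(w2 + 1L, total + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

#' Stability summary of repeated feature selections
#'
#' @param sets List (length >= 2) of character vectors of selected feature
#'   names.
#' @return A list: `intersect`, `union`, `jaccard_of_extremes`
#'   (`|intersection| / |union|`; 1 when all sets are empty),
#'   `mean_pairwise_jaccard`.
#' @export
stability_summary <- function(sets) {
  if (!is.list(sets) || length(sets) < 2)
    sivs_stop("stability_summary() needs at least two sets",
              class = "sivsel_parameter_error")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  inter <- Reduce(intersect, sets)
  uni <- Reduce(union, sets)
  jaccard <- function(a, b) {
    u <- union(a, b)
    if (length(u) == 0) 1 else length(intersect(a, b)) / length(u)
  }
  pairs <- utils::combn(length(sets), 2)
  mean_pw <- mean(apply(pairs, 2, function(ij)
    jaccard(sets[[ij[1]]], sets[[ij[2]]])))
  list(intersect = inter, union = uni,
       jaccard_of_extremes = if (length(uni) == 0) 1
                             else length(inter) / length(uni),
       mean_pairwise_jaccard = mean_pw)
}
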