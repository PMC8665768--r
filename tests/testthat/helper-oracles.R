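# Independent oracles, kept deliberately naive and separate from the
# package's implementations.

# Median via sorting: even length = mean of the two middle order stats.
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# Linear-interpolation quantile (type 7), written out by hand.
oracle_quantile7 <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Brute-force importance score: indicator x median(|c*|) x count / (1 + IQR).
oracle_vimp <- function(cstar) {
  if (length(cstar) == 0) return(0)
  pos <- sum(cstar > 0)
  neg <- sum(cstar < 0)
  ind <- if (pos == length(cstar) || neg == length(cstar)) 1 else 0
  if (ind == 0) return(0)
  iqr <- oracle_quantile7(cstar, 0.75) - oracle_quantile7(cstar, 0.25)
  oracle_median(abs(cstar)) * length(cstar) / (1 + iqr)
}

# Exhaustive pair-counting AUROC: ties count one half.
oracle_auroc <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments
# over the realized (midrank) rank vector.
oracle_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d), ties.method = "average")
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  ws <- as.matrix(signs) %*% r
  p_le <- mean(ws <= w_obs + 1e-12)
  p_ge <- mean(ws >= w_obs - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}

# Bootstrap estimate of the two-sided p for an AUROC difference on paired
# scores: stratified resampling within classes, normal reference with the
# bootstrap standard error.
oracle_delong_bootstrap_p <- function(y, sa, sb, B = 10000, seed = 1) {
  set.seed(seed)
  pos <- which(y == 1)
  neg <- which(y == 0)
  d_obs <- auroc(y, sa) - auroc(y, sb)
  diffs <- replicate(B, {
    idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    auroc(y[idx], sa[idx]) - auroc(y[idx], sb[idx])
  })
  se <- sd(diffs)
  if (se == 0) return(if (d_obs == 0) 1 else 0)
  2 * pnorm(-abs(d_obs) / se)
}
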