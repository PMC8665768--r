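test_that("AUROC matches hand-enumerated and degenerate cases", {
  expect_equal(auroc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(auroc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_error(auroc(c(1, 1), c(0.1, 0.2)), "classes")
  expect_error(auroc(c(1, 0), c(0.1)), "length")
})

test_that("AUROC equals the pair-counting oracle, with ties", {
  set.seed(12)
  for (i in 1:40) {
    n <- sample(5:60, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(round(runif(n), 2), n, replace = TRUE)  # many ties
    expect_identical(auroc(y, s), oracle_auroc(y, s))
  }
})

test_that("score complement flips AUROC when tie-free", {
  set.seed(3)
  y <- rbinom(40, 1, 0.5)
  y[1:2] <- c(0, 1)
  s <- rnorm(40)
  expect_equal(auroc(y, s) + auroc(y, -s), 1)
})

test_that("paired AUROC comparison behaves at its edges", {
  set.seed(5)
  y <- rep(c(0, 1), each = 15)
  s <- rnorm(30)
  same <- delong_paired_test(y, s, s)
  expect_equal(same$p, 1)
  expect_equal(same$auroc_a, same$auroc_b)

  s2 <- rnorm(30)
  ab <- delong_paired_test(y, s, s2)
  ba <- delong_paired_test(y, s2, s)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
})

test_that("paired AUROC comparison matches the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  for (i in 1:10) {
    y <- c(0, 1, rbinom(38, 1, 0.5))
    base <- rnorm(40)
    sa <- y + base + rnorm(40)
    sb <- 0.5 * y + base * 0.5 + rnorm(40)
    ours <- delong_paired_test(y, sa, sb)
    mk_roc <- function(s) pROC::roc(y, s, quiet = TRUE, direction = "<",
                                    levels = c("0", "1"))
    ref <- pROC::roc.test(mk_roc(sa), mk_roc(sb),
                          method = "delong", paired = TRUE)
    expect_equal(ours$p, as.numeric(ref$p.value), tolerance = 1e-9)
  }
})

test_that("with an independent arm the paired variance loses its covariance", {
  set.seed(21)
  y <- rep(c(0, 1), each = 100)
  sa <- y + rnorm(200)
  sb <- rnorm(200)  # unrelated noise
  pa <- sivsel:::delong_placements(y, sa)
  pb <- sivsel:::delong_placements(y, sb)
  cov10 <- cov(pa$v10, pb$v10)
  expect_lt(abs(cov10), 0.02)
})

test_that("signed-rank test matches exact conventions", {
  # unanimous shift of six pairs: the most extreme of 2^6 sign patterns
  x <- c(5, 6, 7, 8, 9, 10)
  expect_equal(paired_wilcoxon(x + 1, x)$p, 2 / 64)
  # identical vectors degenerate to p = 1 with a warning
  expect_warning(res <- paired_wilcoxon(x, x), "zero")
  expect_equal(res$p, 1)
})

test_that("signed-rank p equals sign-flip enumeration on small samples", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    x <- sample(0:12, n, replace = TRUE)
    y <- sample(0:12, n, replace = TRUE)
    if (all(x == y)) x[1] <- x[1] + 1
    expect_equal(paired_wilcoxon(x, y)$p, oracle_signed_rank_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("signed-rank test agrees with the reference for tie-free pairs", {
  set.seed(41)
  x <- rnorm(15)
  y <- rnorm(15)
  ours <- paired_wilcoxon(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(ours$p, as.numeric(ref$p.value), tolerance = 1e-12)
})

test_that("stability summaries follow set arithmetic", {
  s <- stability_summary(list(c("a", "b"), c("b", "c")))
  expect_equal(s$intersect, "b")
  expect_setequal(s$union, c("a", "b", "c"))
  expect_equal(s$jaccard_of_extremes, 1 / 3)
  expect_equal(s$mean_pairwise_jaccard, 1 / 3)

  same <- stability_summary(list(c("x", "y"), c("y", "x"), c("x", "y")))
  expect_equal(same$jaccard_of_extremes, 1)
  expect_equal(same$mean_pairwise_jaccard, 1)

  disjoint <- stability_summary(list("a", "b"))
  expect_equal(disjoint$jaccard_of_extremes, 0)

  empty <- stability_summary(list(character(0), character(0)))
  expect_equal(empty$jaccard_of_extremes, 1)
  expect_error(stability_summary(list("a")), "at least two")
})

test_that("the study harness produces coherent paired reports", {
  d <- generate_dataset(synthetic_spec(n_train = 120, n_valid = 80, p = 30,
                                       n_informative = 3, effect_size = 2.0,
                                       seed = 71))
  parts <- split_train_valid(d, 80, seed = 71)
  cfg <- fast_config(iterations = 8, rfe_repeats = 4, master_seed = 19)
  st <- run_study(parts$train, parts$valid, n_runs = 3, config = cfg)
  expect_length(st$sets$plain, 3)
  expect_length(st$sets$sivs, 3)
  expect_equal(nrow(st$delong), 3)
  expect_length(st$wilcoxon_p, 1)
  # restricted-arm selections stay inside the stable set
  k_sel <- length(st$sivs_result$selected_features)
  expect_true(all(st$feature_counts$sivs <= k_sel))
  for (arm in c("plain", "sivs")) {
    stab <- st$stability[[arm]]
    for (set in st$sets[[arm]]) {
      expect_true(all(stab$intersect %in% set))
      expect_true(all(set %in% stab$union))
    }
  }
  # summary table is consistent with the raw vectors
  med_plain <- st$summary[st$summary$arm == "plain" &
                          st$summary$metric == "feature_count", "median"]
  expect_equal(med_plain, median(st$feature_counts$plain))
})
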