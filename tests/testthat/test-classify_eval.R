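brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

test_that("metrics match hand-worked examples", {
  m <- compute_metrics(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
  expect_equal(m$auc, 1); expect_equal(m$accuracy, 1)
  expect_equal(m$sensitivity, 1); expect_equal(m$specificity, 1)
  m2 <- compute_metrics(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))
  expect_equal(m2$auc, 0.75)
  expect_equal(compute_metrics(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  expect_error(compute_metrics(runif(4), rep(1, 4)), class = "gaitxai_one_class_error")
})

test_that("rank-form AUC equals brute-force concordant-pair counting", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(4:60, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # some heavy ties
    expect_equal(gaitxai:::auc_mann_whitney(scores, labels),
                 brute_auc(scores, labels))
  }
})

test_that("subject aggregation averages windows and is order invariant", {
  probs <- c(0.2, 0.4, 0.9)
  sl <- subject_level(probs, c("a", "a", "b"), c(0, 0, 1))
  expect_equal(sl$probability[sl$subject_id == "a"], 0.3)
  expect_equal(sl$probability[sl$subject_id == "b"], 0.9)
  perm <- c(3, 1, 2)
  expect_equal(subject_level(probs[perm], c("a", "a", "b")[perm], c(0, 0, 1)[perm]), sl)
  expect_error(subject_level(probs, c("a", "a", "a"), c(0, 1, 0)), "inconsistent")
})

test_that("repeat aggregation reports mean, sample SD, and a bootstrap CI containing the mean", {
  ms <- function(a) structure(list(auc = a, accuracy = a, sensitivity = a,
                                   specificity = a), class = "metric_set")
  agg <- aggregate_repeats(lapply(rep(0.9, 5), ms))
  expect_equal(agg$mean, rep(0.9, 4))
  expect_equal(agg$sd, rep(0, 4))
  expect_equal(agg$ci_lower, rep(0.9, 4)); expect_equal(agg$ci_upper, rep(0.9, 4))
  agg2 <- aggregate_repeats(lapply(c(0.8, 0.9), ms))
  expect_equal(agg2$mean[1], 0.85)
  expect_equal(agg2$sd[1], sd(c(0.8, 0.9)))
  expect_error(aggregate_repeats(list(ms(0.9))), class = "gaitxai_repeats_error")
  set.seed(2)
  for (i in 1:25) {
    vals <- runif(sample(3:8, 1))
    a <- aggregate_repeats(lapply(vals, ms), n_boot = 500, seed = i)
    expect_lte(a$ci_lower[1], a$mean[1])
    expect_gte(a$ci_upper[1], a$mean[1])
  }
})

test_that("exact paired Wilcoxon matches enumeration and is symmetric", {
  a <- c(0.95, 0.93, 0.92, 0.96, 0.94)
  b <- a - c(0.01, 0.02, 0.015, 0.03, 0.005)
  w <- paired_wilcoxon(a, b)
  expect_equal(w$p_one_sided, 1 / 32)
  expect_equal(w$p_two_sided, 2 / 32)
  expect_equal(w$statistic, 15)
  # identical vectors -> degenerate p = 1
  expect_equal(paired_wilcoxon(a, a)$p_two_sided, 1)
  # sign flip swaps the one-sided tail
  wf <- paired_wilcoxon(b, a)
  expect_equal(wf$p_one_sided, 1)  # P(W+ >= 0) = 1 in the flipped direction
  expect_equal(wf$p_two_sided, w$p_two_sided)
  # agreement with stats::wilcox.test exact p on tie-free cases
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    ours <- paired_wilcoxon(x, y)
    ref1 <- wilcox.test(x, y, paired = TRUE, alternative = "greater", exact = TRUE)
    ref2 <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(ours$p_one_sided, ref1$p.value)
    expect_equal(ours$p_two_sided, ref2$p.value)
  }
  # tied absolute differences fall back to enumeration, p in (0, 1]
  wt <- paired_wilcoxon(c(1, 2, 3, 4, 6), c(0, 1, 2, 3, 4))
  expect_gt(wt$p_one_sided, 0); expect_lte(wt$p_two_sided, 1)
})
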