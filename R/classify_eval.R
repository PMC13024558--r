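# Window- and subject-level classification metrics, repeat aggregation
# with empirical confidence intervals, and exact paired Wilcoxon model
# comparison.

# AUC in the Mann-Whitney probability form; ties count one half.
auc_mann_whitney <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop_gaitxai("AUC undefined: only one class present", class = "gaitxai_one_class_error")
  }
  r <- rank(scores)                     # average ranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics for one evaluation
#'
#' AUC uses the Mann-Whitney probability form (tied scores count one
#' half); accuracy, sensitivity and specificity are taken at a fixed
#' decision threshold.
#'
#' @param probabilities Predicted PD probabilities.
#' @param labels 0/1 labels (1 = PD).
#' @param threshold Decision threshold (default 0.5).
#' @param level Annotation only: `"window"` or `"subject"`.
#' @return A `metric_set`: list with auc, accuracy, sensitivity,
#'   specificity, threshold, level and the confusion matrix counts.
#' @export
compute_metrics <- function(probabilities, labels, threshold = 0.5,
                            level = c("window", "subject")) {
  level <- match.arg(level)
  assert_that(length(probabilities) == length(labels), "compute_metrics: length mismatch")
  auc <- auc_mann_whitney(probabilities, labels)
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
  structure(list(auc = auc,
                 accuracy = (tp + tn) / length(labels),
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 threshold = threshold, level = level,
                 confusion = c(tp = tp, fp = fp, tn = tn, fn = fn)),
            class = "metric_set")
}

#' Aggregate window predictions to subjects
#'
#' A subject's probability is the mean of its window probabilities; its
#' label is its (single) group label. Invariant to window order.
#'
#' @param probabilities Window probabilities.
#' @param subject_ids Window subject ids.
#' @param labels Window labels.
#' @return Data frame (subject_id, probability, label), one row per
#'   subject, ordered by subject_id.
#' @export
subject_level <- function(probabilities, subject_ids, labels) {
  nlab <- tapply(labels, subject_ids, function(l) length(unique(l)))
  assert_that(all(nlab == 1), "subject_level: inconsistent labels within subject(s): %s",
              paste(names(nlab)[nlab > 1], collapse = ", "))
  agg <- tapply(probabilities, subject_ids, mean)
  lab <- tapply(labels, subject_ids, function(l) l[1])
  ids <- sort(names(agg))
  data.frame(subject_id = ids, probability = as.numeric(agg[ids]),
             label = as.integer(lab[ids]), row.names = NULL)
}

#' Summarize repeated evaluations
#'
#' Mean, sample SD and empirical 95% CI per metric across repeats. The CI
#' is a seeded percentile bootstrap of the mean (10^4 resamples,
#' 2.5/97.5 percentiles).
#'
#' @param metric_sets List of [compute_metrics()] results (>= 2 repeats).
#' @param n_boot Bootstrap resamples.
#' @param seed Bootstrap seed.
#' @return Data frame with one row per metric: mean, sd, ci_lower,
#'   ci_upper, n_repeats.
#' @export
aggregate_repeats <- function(metric_sets, n_boot = 10000L, seed = 1L) {
  assert_that(length(metric_sets) >= 2,
              "aggregate_repeats: need >= 2 repeats for an SD", class = "gaitxai_repeats_error")
  metrics <- c("auc", "accuracy", "sensitivity", "specificity")
  vals <- sapply(metrics, function(m) vapply(metric_sets, `[[`, numeric(1), m))
  with_seed(seed, {
    out <- lapply(metrics, function(m) {
      v <- vals[, m]
      boots <- vapply(seq_len(n_boot),
                      function(i) mean(v[sample.int(length(v), replace = TRUE)]), numeric(1))
      data.frame(metric = m, mean = mean(v), sd = stats::sd(v),
                 ci_lower = as.numeric(stats::quantile(boots, 0.025)),
                 ci_upper = as.numeric(stats::quantile(boots, 0.975)),
                 n_repeats = length(v))
    })
  })
  do.call(rbind, out)
}

# exact null distribution of W+ for (possibly tied) absolute-value ranks;
# enumerates the 2^n sign patterns (n kept small by the caller)
signrank_enumerate <- function(ranks) {
  n <- length(ranks)
  stats <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    stats[mask + 1] <- sum(ranks[bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L])
  }
  stats
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Zeros are dropped, tied absolute differences receive average ranks, and
#' the null distribution is exact (signed-rank enumeration / psignrank)
#' for n <= 20 after zero-removal, with a tie-corrected normal
#' approximation beyond. One-sided p is for the alternative
#' `median(a - b) > 0`; reporting both sidednesses makes the n = 5
#' floor of the two-sided test (0.0625) visible.
#'
#' @param a,b Paired metric vectors (same length, paired by split).
#' @return List with `statistic` (W+, sum of positive ranks),
#'   `p_one_sided`, `p_two_sided`, `n_effective`.
#' @export
paired_wilcoxon <- function(a, b) {
  assert_that(length(a) == length(b), "paired_wilcoxon: unequal lengths")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = 0, p_one_sided = 1, p_two_sided = 1, n_effective = 0L))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (!ties && n <= 25) {
    # integer ranks: exact distribution from psignrank
    p_ge <- stats::psignrank(w - 1, n, lower.tail = FALSE)
    p_le <- stats::psignrank(w, n)
  } else if (n <= 20) {
    null_w <- signrank_enumerate(r)
    p_ge <- mean(null_w >= w)
    p_le <- mean(null_w <= w)
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    p_ge <- stats::pnorm((w - mu) / sigma, lower.tail = FALSE)
    p_le <- stats::pnorm((w - mu) / sigma)
  }
  list(statistic = w,
       p_one_sided = min(1, p_ge),
       p_two_sided = min(1, 2 * min(p_ge, p_le)),
       n_effective = n)
}
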