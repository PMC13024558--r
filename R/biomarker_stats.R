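# Data-level validation of consensus features: Mann-Whitney U with exact
# small-sample p, Cliff's delta effect size (PD - CO orientation),
# Benjamini-Hochberg FDR, and group median/IQR summaries computed from
# raw (unnormalized) window features.

#' Mann-Whitney U test
#'
#' U counts pairs with `x > y` plus half the tied pairs (computed via
#' average ranks). The two-sided p-value is exact — full enumeration of
#' the permutation distribution, which handles ties — when
#' `min(n, m) <= 8` and `choose(n + m, n) <= 20000`, and a tie-corrected
#' normal approximation with continuity correction otherwise.
#'
#' @param x,y Numeric samples (x = PD, y = CO in pipeline use).
#' @return List with `u`, `p_value`, `exact` (logical).
#' @export
mann_whitney_u <- function(x, y) {
  assert_that(length(x) > 0 && length(y) > 0, "mann_whitney_u: empty sample")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  exact <- min(nx, ny) <= 8 && choose(nx + ny, nx) <= 20000
  if (exact) {
    null_u <- apply(utils::combn(nx + ny, nx), 2L, function(idx) {
      sum(r[idx]) - nx * (nx + 1) / 2
    })
    mu <- nx * ny / 2
    p <- mean(abs(null_u - mu) >= abs(u - mu) - 1e-12)
  } else {
    mu <- nx * ny / 2
    n <- nx + ny
    tie_tab <- table(r)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * (n + 1 - tie_term)
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(z, lower.tail = FALSE)
  }
  list(u = u, p_value = min(1, p), exact = exact)
}

#' Cliff's delta effect size
#'
#' `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (n_x n_y)`, in [-1, 1];
#' pipeline orientation is x = PD, y = CO, so negative values mean PD
#' below control. Computed from average ranks, equivalent to pair
#' enumeration for any tie structure.
#'
#' @param x,y Numeric samples.
#' @return Numeric delta.
#' @export
cliffs_delta <- function(x, y) {
  assert_that(length(x) > 0 && length(y) > 0, "cliffs_delta: empty sample")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2   # #{x>y} + 0.5 #ties
  (2 * u - nx * ny) / (nx * ny)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, `adj_(i) = min_(j >= i) p_(j) * m / j`
#' clipped to 1, in the input order.
#'
#' @param p Raw p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(p) {
  assert_that(length(p) > 0, "bh_fdr: empty p-value vector")
  assert_that(all(is.finite(p)) && all(p >= 0 & p <= 1), "bh_fdr: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Group summary and tests for one feature
#'
#' Medians and IQR (Q3 - Q1, linear-interpolation quantiles), Mann-Whitney
#' p and Cliff's delta with PD - CO orientation.
#'
#' @param control,pd Raw feature values for the control and PD groups.
#' @return One-row data frame: control_median, control_iqr, pd_median,
#'   pd_iqr, p_value, cliffs_delta.
#' @export
summarize_feature <- function(control, pd) {
  assert_that(length(control) > 0 && length(pd) > 0, "summarize_feature: empty group")
  mw <- mann_whitney_u(pd, control)
  data.frame(
    control_median = stats::median(control),
    control_iqr = unname(diff(stats::quantile(control, c(0.25, 0.75), type = 7))),
    pd_median = stats::median(pd),
    pd_iqr = unname(diff(stats::quantile(pd, c(0.25, 0.75), type = 7))),
    p_value = mw$p_value,
    cliffs_delta = cliffs_delta(pd, control))
}

#' Biomarker validation table for a set of features
#'
#' Tests each feature in a raw window-feature matrix between groups and
#' applies BH-FDR within the supplied feature family (in pipeline use,
#' the consensus set only). The sampling unit defaults to windows,
#' matching the raw-unit group summaries; `unit = "subject"` first
#' averages windows within subject, which is the unit on which the test's
#' independence assumption holds.
#'
#' @param tokens `token_dataset` with raw features and labels.
#' @param features Feature names to test (default all 36).
#' @param unit `"window"` or `"subject"`.
#' @return A `biomarker_table` data frame, one row per feature, with
#'   group medians/IQRs, raw and FDR-adjusted p-values and Cliff's delta
#'   (PD - CO).
#' @export
biomarker_validation <- function(tokens, features = feature_names(),
                                 unit = c("window", "subject")) {
  unit <- match.arg(unit)
  raw <- tokens$raw[, features, drop = FALSE]
  lab <- tokens$meta$label
  if (unit == "subject") {
    raw <- rowsum(raw, tokens$meta$subject_id) /
      as.vector(table(tokens$meta$subject_id)[sort(unique(tokens$meta$subject_id))])
    lab <- tapply(tokens$meta$label, tokens$meta$subject_id, `[`, 1)[rownames(raw)]
  }
  rows <- lapply(features, function(f) {
    cbind(feature = f, summarize_feature(raw[lab == 0, f], raw[lab == 1, f]))
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_fdr(out$p_value)
  out <- out[, c("feature", "control_median", "control_iqr", "pd_median", "pd_iqr",
                 "p_value", "p_adjusted", "cliffs_delta")]
  class(out) <- c("biomarker_table", "data.frame")
  out
}
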