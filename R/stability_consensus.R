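# Stability-based consensus feature selection: top-fraction attribution
# sets per (model, split) experiment, per-feature stability scores across
# experiments, and thresholded consensus features.

#' Top-fraction features of one attribution record
#'
#' Selects the `ceil(fraction * n_features)` features with the largest
#' aggregate attribution; ties at the cut are broken by canonical feature
#' order (the order of [feature_names()]), so selection is deterministic.
#'
#' @param record An `attribution_record` (or data frame with `feature`,
#'   `aggregate`).
#' @param fraction Fraction of features to keep (0 < fraction <= 1);
#'   0.2 on 36 features keeps 8.
#' @return Character vector of selected feature names.
#' @export
top_fraction_features <- function(record, fraction = 0.2) {
  assert_that(fraction > 0 && fraction <= 1, "top_fraction_features: fraction must be in (0,1]")
  assert_that(nrow(record) > 0, "top_fraction_features: empty attribution record")
  k <- ceiling(fraction * nrow(record))
  canonical <- match(record$feature, feature_names())
  ord <- order(-record$aggregate, canonical)
  record$feature[ord[seq_len(k)]]
}

#' Stability scores across experiments
#'
#' The stability score of a feature is the fraction of experiments
#' (repeated splits x model architectures) whose top-attribution set
#' contains it; invariant to experiment order.
#'
#' @param subsets List of feature-name vectors, one per experiment.
#' @param features Universe of features (defaults to [feature_names()]).
#' @return A `stability_table` data frame: feature, count, n_experiments,
#'   score.
#' @export
stability_scores <- function(subsets, features = feature_names()) {
  assert_that(length(subsets) >= 1, "stability_scores: need at least one experiment")
  count <- vapply(features, function(f) {
    sum(vapply(subsets, function(s) f %in% s, logical(1)))
  }, numeric(1))
  out <- data.frame(feature = features, count = as.integer(count),
                    n_experiments = length(subsets),
                    score = count / length(subsets),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("stability_table", "data.frame")
  out
}

#' Consensus features at a stability threshold
#'
#' Features whose score is greater than *or equal to* the threshold
#' (the "20% or more" rule is inclusive), ordered by descending score
#' with canonical-name tie-break.
#'
#' @param table A [stability_scores()] result.
#' @param threshold Stability threshold in (0, 1].
#' @return The consensus subset of the table, with a `consensus` column;
#'   zero rows (not an error) when nothing reaches the threshold.
#' @export
consensus_features <- function(table, threshold = 0.2) {
  assert_that(threshold > 0 && threshold <= 1, "consensus_features: threshold must be in (0,1]")
  canonical <- match(table$feature, feature_names())
  keep <- table$score >= threshold
  out <- table[keep, , drop = FALSE]
  out <- out[order(-out$score, canonical[keep]), , drop = FALSE]
  out$consensus <- rep(TRUE, nrow(out))
  row.names(out) <- NULL
  out
}
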