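# Repeated subject-wise grouped 70/15/15 partitioning with hard leakage
# guarantees. The unit of assignment is the subject, stratified by group,
# with largest-remainder rounding of the per-class partition counts.

PARTITIONS <- c("train", "val", "test")

largest_remainder <- function(n, ratios) {
  raw <- n * ratios
  base <- floor(raw)
  rem <- raw - base
  left <- n - sum(base)
  if (left > 0) {
    # ties broken by partition order (train, val, test)
    ord <- order(rem, -seq_along(rem), decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Subject-wise stratified split
#'
#' Assigns every subject to exactly one of train/validation/test,
#' stratified by group so both classes appear in every partition.
#' Deterministic for a given seed.
#'
#' @param table A [subject_table()].
#' @param ratios Numeric length-3 vector of train/val/test fractions
#'   (must sum to 1).
#' @param seed Integer seed.
#' @return A `split_plan` with `seed`, `assignment` (named character
#'   vector subject_id -> partition) and `realized` fraction table.
#' @export
make_split <- function(table, ratios = c(0.7, 0.15, 0.15), seed = 1L) {
  assert_that(length(ratios) == 3 && abs(sum(ratios) - 1) < 1e-8,
              "make_split: ratios must be three fractions summing to 1")
  assignment <- character(0)
  for (g in c("CO", "PD")) {
    ids <- table$subject_id[table$group == g]
    assert_that(length(ids) >= 3, "make_split: need >= 3 %s subjects, have %d", g, length(ids))
    counts <- largest_remainder(length(ids), ratios)
    if (any(counts == 0)) {
      stop_gaitxai("make_split: ratios leave an empty partition for class %s", g,
                   class = "gaitxai_split_error")
    }
    ids <- with_seed(derive_seed(seed, paste0("split_", g)), sample(ids))
    assignment[ids] <- rep(PARTITIONS, counts)
  }
  assignment <- assignment[order(names(assignment))]
  realized <- prop.table(table(factor(assignment, levels = PARTITIONS)))
  structure(list(seed = as.integer(seed), assignment = assignment,
                 realized = realized), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  tab <- table(factor(x$assignment, levels = PARTITIONS))
  cat(sprintf("<split_plan> seed=%d  train=%d val=%d test=%d subjects\n",
              x$seed, tab[["train"]], tab[["val"]], tab[["test"]]))
  invisible(x)
}

#' Repeated subject-wise splits with consecutive seeds
#'
#' @param table A [subject_table()].
#' @param ratios Train/val/test fractions.
#' @param n_repeats Number of repeated splits (5 in the reference design).
#' @param base_seed Seed of the first split; split k uses `base_seed + k - 1`.
#' @return List of `split_plan` objects.
#' @export
make_repeated_splits <- function(table, ratios = c(0.7, 0.15, 0.15),
                                 n_repeats = 5L, base_seed = 1L) {
  assert_that(n_repeats >= 1, "make_repeated_splits: n_repeats must be >= 1")
  lapply(seq_len(n_repeats), function(k) make_split(table, ratios, base_seed + k - 1L))
}

#' Assert that windowed data respects a subject-wise split
#'
#' Fails iff some subject's windows occur in two or more partitions.
#'
#' @param plan A `split_plan`, or any named vector/list mapping subject_id
#'   to partition labels per window (to audit arbitrary assignments, pass
#'   `window_partitions` explicitly).
#' @param tokens A `token_dataset` whose windows carry subject ids.
#' @param window_partitions Optional character vector: the partition each
#'   window was actually placed in. Defaults to the plan assignment of the
#'   window's subject (which is leakage-free by construction).
#' @return Invisibly, a list `(pass, offenders)`; raises an error naming
#'   the offending subjects when leakage is detected.
#' @export
assert_no_leakage <- function(plan, tokens, window_partitions = NULL) {
  sid <- tokens$meta$subject_id
  if (is.null(window_partitions)) {
    missing_ids <- setdiff(unique(sid), names(plan$assignment))
    assert_that(length(missing_ids) == 0,
                "assert_no_leakage: subjects missing from plan: %s",
                paste(missing_ids, collapse = ", "))
    window_partitions <- unname(plan$assignment[sid])
  }
  nparts <- tapply(window_partitions, sid, function(p) length(unique(p)))
  offenders <- names(nparts)[nparts > 1]
  if (length(offenders) > 0) {
    stop_gaitxai("subject-level leakage: windows of %s appear in multiple partitions",
                 paste(offenders, collapse = ", "), class = "gaitxai_leakage_error")
  }
  invisible(list(pass = TRUE, offenders = character(0)))
}

#' Serialize a split plan to JSON for audit
#'
#' @param plan A `split_plan`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(list(seed = plan$seed, assignment = as.list(plan$assignment)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
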