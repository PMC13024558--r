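demo_table <- function(n_co = 10, n_pd = 10) {
  subject_table(data.frame(
    subject_id = c(sprintf("C%02d", seq_len(n_co)), sprintf("P%02d", seq_len(n_pd))),
    group = rep(c("CO", "PD"), c(n_co, n_pd)),
    hy_stage = rep(c(0, 2), c(n_co, n_pd))))
}

test_that("splits follow largest-remainder rounding per class and are deterministic", {
  tab <- demo_table(10, 10)
  plan <- make_split(tab, c(0.7, 0.15, 0.15), seed = 4)
  counts <- table(plan$assignment)
  expect_equal(sum(counts), 20)
  # per class: 7/1.5/1.5 -> 7 train, and 2/1 or 1/2 between val/test
  for (g in c("C", "P")) {
    gcounts <- table(plan$assignment[grepl(g, names(plan$assignment))])
    expect_equal(unname(gcounts[["train"]]), 7)
    expect_setequal(as.integer(gcounts[c("val", "test")]), c(2, 1))
  }
  expect_identical(make_split(tab, seed = 4)$assignment, plan$assignment)
  expect_false(identical(make_split(tab, seed = 5)$assignment, plan$assignment))
})

test_that("degenerate ratios and tiny classes are rejected", {
  tab <- demo_table(10, 10)
  expect_error(make_split(tab, c(1, 0, 0)), class = "gaitxai_split_error")
  expect_error(make_split(demo_table(2, 10)), ">= 3")
})

test_that("repeated splits use consecutive seeds and differ", {
  tab <- demo_table(12, 12)
  plans <- make_repeated_splits(tab, n_repeats = 5, base_seed = 100)
  expect_length(plans, 5)
  expect_equal(vapply(plans, `[[`, integer(1), "seed"), 100:104)
  tests <- lapply(plans, function(p) sort(names(p$assignment)[p$assignment == "test"]))
  expect_gt(length(unique(tests)), 1)
  expect_length(make_repeated_splits(tab, n_repeats = 1), 1)
})

test_that("every generated plan partitions subjects with stratification", {
  tab <- demo_table(11, 17)
  for (seed in 1:100) {
    plan <- make_split(tab, seed = seed)
    expect_setequal(names(plan$assignment), tab$subject_id)
    expect_true(all(table(plan$assignment) > 0))
    for (g in c("CO", "PD")) {
      ids <- tab$subject_id[tab$group == g]
      frac <- prop.table(table(factor(plan$assignment[ids],
                                      levels = c("train", "val", "test"))))
      expect_true(all(abs(frac - c(0.7, 0.15, 0.15)) < 1 / length(ids) + 1e-9))
      expect_true(all(table(factor(plan$assignment[ids],
                                   levels = c("train", "val", "test"))) >= 1))
    }
  }
})

test_that("leakage assertion passes clean plans and catches contaminated ones", {
  tk <- blob_tokens(n_subj = 6, n_win = 4)
  tab <- subject_table(data.frame(
    subject_id = unique(tk$meta$subject_id),
    group = ifelse(tapply(tk$meta$label, tk$meta$subject_id, `[`, 1)[
      unique(tk$meta$subject_id)] == 1, "PD", "CO"),
    hy_stage = ifelse(tapply(tk$meta$label, tk$meta$subject_id, `[`, 1)[
      unique(tk$meta$subject_id)] == 1, 2, 0)))
  plan <- make_split(tab, seed = 1)
  expect_silent(assert_no_leakage(plan, tk))
  # duplicate one subject's windows into another partition
  parts <- unname(plan$assignment[tk$meta$subject_id])
  offender <- names(plan$assignment)[plan$assignment == "train"][1]
  parts[which(tk$meta$subject_id == offender)[1]] <- "test"
  expect_error(assert_no_leakage(plan, tk, window_partitions = parts),
               class = "gaitxai_leakage_error")
  expect_error(assert_no_leakage(plan, tk, window_partitions = parts), offender)
})

test_that("record-wise (window-level) random splitting is caught as leakage", {
  tk <- blob_tokens(n_subj = 6, n_win = 6)
  tab <- subject_table(data.frame(
    subject_id = unique(tk$meta$subject_id),
    group = rep(c("CO", "PD"), each = 6),
    hy_stage = rep(c(0, 2), each = 6)))
  plan <- make_split(tab, seed = 2)
  set.seed(9)
  random_parts <- sample(c("train", "val", "test"), nrow(tk$meta),
                         replace = TRUE, prob = c(0.7, 0.15, 0.15))
  expect_error(assert_no_leakage(plan, tk, window_partitions = random_parts),
               class = "gaitxai_leakage_error")
})
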