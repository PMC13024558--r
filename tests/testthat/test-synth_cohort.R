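test_that("cohort generation is deterministic given the seed", {
  cfg <- cohort_config(n_control = 3, n_pd = 3, record_seconds = 6, seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$table, b$table)
  expect_identical(a$truth, b$truth)
  expect_identical(lapply(a$signals, `[[`, "channels"),
                   lapply(b$signals, `[[`, "channels"))
})

test_that("default cohort matches the reference group sizes", {
  cfg <- cohort_config(record_seconds = 1)  # sizes only; keep records tiny
  expect_equal(cfg$n_control, 73L)
  expect_equal(cfg$n_pd, 93L)
  ch <- generate_cohort(cohort_config(n_control = 73, n_pd = 93, record_seconds = 1))
  expect_equal(nrow(ch$table), 166L)
  expect_equal(sum(ch$table$group == "PD"), 93L)
  expect_equal(sum(ch$table$group == "CO"), 73L)
  # H&Y distribution of the defaults centres near 2.3 with SD near 0.6
  hy <- ch$table$hy_stage[ch$table$group == "PD"]
  expect_gt(mean(hy), 2.0); expect_lt(mean(hy), 2.6)
  expect_gt(sd(hy), 0.4); expect_lt(sd(hy), 0.8)
})

test_that("record length equals duration times sampling rate", {
  ch <- small_cohort(n_co = 1, n_pd = 1, seconds = 30, seed = 5)
  expect_equal(nrow(ch$signals[[1]]$channels), 3000L)
})

test_that("noiseless constant-amplitude subject produces identical cycles", {
  cfg <- cohort_config(n_control = 1, n_pd = 0, record_seconds = 8,
                       amp_cv_control = 0, cycle_jitter_cv = 0,
                       stride_period_sd = 0, noise_sd = 0, seed = 3,
                       variability_suppression = 0, speed_slowing = 0)
  ch <- generate_cohort(cfg)
  x <- ch$signals[[1]]$channels[, 1]
  per <- round(cfg$stride_period_s * cfg$sampling_rate_hz)  # 110 samples
  # compare two interior whole cycles
  c1 <- x[101:(100 + per)]; c2 <- x[(101 + per):(100 + 2 * per)]
  expect_equal(c1, c2, tolerance = 1e-10)
})

test_that("total-force channels equal the sum of their sensors before noise", {
  cfg <- cohort_config(n_control = 1, n_pd = 1, record_seconds = 5,
                       noise_sd = 0, seed = 21)
  ch <- generate_cohort(cfg)
  for (sig in ch$signals) {
    expect_equal(sig$channels[, 17], rowSums(sig$channels[, 1:8]), tolerance = 1e-10)
    expect_equal(sig$channels[, 18], rowSums(sig$channels[, 9:16]), tolerance = 1e-10)
  }
})

test_that("realized amplitude CV decreases monotonically with H&Y stage", {
  cfg <- cohort_config(variability_suppression = 0.3)
  h <- c(0, 1, 1.5, 2, 2.5, 3)
  cv <- cfg$amp_cv_control * (1 - cfg$variability_suppression * h)
  expect_true(all(diff(cv) < 0))
  ch <- small_cohort(n_co = 2, n_pd = 8, seconds = 2, seed = 2,
                     variability_suppression = 0.3)
  expect_equal(ch$truth$amp_cv,
               cfg$amp_cv_control * (1 - 0.3 * ch$truth$hy_stage))
})

test_that("infeasible configurations are rejected", {
  expect_error(cohort_config(variability_suppression = 1.2), class = "gaitxai_config_error")
  expect_error(cohort_config(hy_distribution = data.frame(stage = 3, prob = 0.5)),
               class = "gaitxai_config_error")
  expect_error(cohort_config(record_seconds = 0), class = "gaitxai_config_error")
  # CV must stay positive at the highest stage
  expect_error(cohort_config(amp_cv_control = 0.1, variability_suppression = 0.34,
                             hy_distribution = data.frame(stage = 3, prob = 1)),
               class = "gaitxai_config_error")
})

test_that("null cohorts (beta = gamma = 0) are statistically exchangeable", {
  # two-sample test on a high-signal token feature should be non-significant
  # in the vast majority of seeds
  pvals <- vapply(1:12, function(s) {
    ch <- generate_cohort(cohort_config(n_control = 8, n_pd = 8, record_seconds = 8,
                                        variability_suppression = 0, speed_slowing = 0,
                                        seed = 100 + s))
    plan <- make_split(ch$table, seed = s)
    tk <- tokenize_cohort(ch$signals, ch$table, plan, window_config())
    bio <- biomarker_validation(tk$tokens, features = "sensor_1_std", unit = "subject")
    bio$p_value
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
})
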