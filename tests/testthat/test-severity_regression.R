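test_that("the bundled worked example reproduces the headline metrics", {
  ex <- severity_worked_example()
  m <- regression_metrics(ex$actual_hy, ex$predicted_hy)
  expect_equal(round(m$mae, 3), 0.158)
  expect_equal(round(m$rmse, 3), 0.241)
  expect_equal(round(m$r2, 3), 0.953)
  expect_equal(round(m$spearman_rho, 3), 0.921)
  expect_lt(m$rho_p, 0.001)
})

test_that("regression metrics honor their definitions and degeneracies", {
  a <- c(0, 1, 2, 3)
  m <- regression_metrics(a, a)
  expect_equal(unlist(m[c("mae", "rmse")]), c(mae = 0, rmse = 0))
  expect_equal(m$r2, 1); expect_equal(m$spearman_rho, 1)
  mc <- regression_metrics(a, rep(mean(a), 4))
  expect_equal(mc$r2, 0)
  expect_error(regression_metrics(rep(2, 4), a), class = "gaitxai_degenerate_error")
  # mae <= rmse always (Jensen)
  set.seed(1)
  for (i in 1:25) {
    act <- rnorm(10); pred <- rnorm(10)
    mm <- regression_metrics(act, pred)
    expect_lte(mm$mae, mm$rmse + 1e-12)
  }
})

test_that("effect size f2 follows r2/(1-r2)", {
  expect_equal(effect_size_f2(0.5), 1)
  expect_equal(effect_size_f2(0), 0)
  expect_equal(effect_size_f2(0.953), 0.953 / 0.047, tolerance = 1e-12)
  expect_gt(effect_size_f2(0.953), 20)
  expect_error(effect_size_f2(1), "r2")
})

test_that("post hoc power is alpha at f2 = 0, monotone in n, and matches Monte Carlo", {
  expect_equal(posthoc_power(0, 50, 5, 0.05), 0.05, tolerance = 1e-12)
  pw <- vapply(c(20, 40, 80, 160), function(n) posthoc_power(0.15, n, 5), numeric(1))
  expect_true(all(diff(pw) > 0))
  expect_error(posthoc_power(0.1, 5, 5), "degrees of freedom")
  # Monte-Carlo oracle: simulate the noncentral F statistic directly
  f2 <- 0.25; n <- 60; p <- 4; alpha <- 0.05
  df1 <- p; df2 <- n - p - 1
  set.seed(99)
  draws <- rchisq(1e5, df1, ncp = f2 * n) / df1 / (rchisq(1e5, df2) / df2)
  mc <- mean(draws > qf(1 - alpha, df1, df2))
  expect_lt(abs(posthoc_power(f2, n, p, alpha) - mc), 0.01)
})

test_that("subject feature vectors aggregate windows invariantly", {
  tk <- blob_tokens(n_subj = 3, n_win = 4, seed = 2)
  sf <- subject_features(tk)
  expect_equal(ncol(sf) - 2, 72)
  expect_equal(nrow(sf), 6)
  # permuting windows leaves the vectors unchanged
  perm <- sample(nrow(tk$meta))
  tkp <- structure(list(meta = tk$meta[perm, ], features = tk$features[perm, ],
                        raw = tk$raw[perm, ]), class = "token_dataset")
  expect_equal(subject_features(tkp), sf)
  # identical windows -> all across-window stds 0
  one <- structure(list(meta = data.frame(subject_id = rep("z", 3), label = 1L),
                        features = tk$features[c(1, 1, 1), ],
                        raw = tk$raw[c(1, 1, 1), ]), class = "token_dataset")
  sf1 <- subject_features(one)
  expect_true(all(abs(sf1[, grep("_wstd$", names(sf1))]) < 1e-5))
  # single window -> means are that window, stds 0
  single <- structure(list(meta = data.frame(subject_id = "q", label = 0L),
                           features = tk$features[2, , drop = FALSE],
                           raw = tk$raw[2, , drop = FALSE]), class = "token_dataset")
  sfs <- subject_features(single)
  expect_equal(unname(unlist(sfs[, paste0(colnames(tk$raw), "_wmean")])),
               unname(tk$raw[2, ]))
  expect_true(all(sfs[, grep("_wstd$", names(sfs))] == 0))
})

test_that("the boosted regressor is deterministic, guards leakage, and fits constants", {
  tk <- blob_tokens(n_subj = 10, n_win = 5, seed = 3)
  sf <- subject_features(tk)
  sf$hy_stage <- 1.5
  fit <- train_severity_model(sf, list(nrounds = 20, seed = 5))
  pred <- predict_severity(fit, sf, allow_train_subjects = TRUE)
  expect_lt(max(abs(pred - 1.5)), 1e-3)  # constant target
  fit2 <- train_severity_model(sf, list(nrounds = 20, seed = 5))
  expect_identical(predict_severity(fit2, sf, allow_train_subjects = TRUE), pred)
  expect_error(predict_severity(fit, sf[1, ]), class = "gaitxai_leakage_error")
  expect_error(train_severity_model(sf[1:3, ]), ">= 5")
})

test_that("a noiseless monotone target is recovered with high rank correlation", {
  tk <- blob_tokens(n_subj = 40, n_win = 6, seed = 4)
  sf <- subject_features(tk)
  sf$hy_stage <- 2 + 0.8 * scale(sf$sensor_1_std_wmean)[, 1]  # monotone in one feature
  set.seed(17)
  test_idx <- sample(nrow(sf), 20)
  train <- sf[-test_idx, ]; test <- sf[test_idx, ]
  fit <- train_severity_model(train, list(nrounds = 250, seed = 1))
  pred <- predict_severity(fit, test)
  expect_gte(cor(rank(test$hy_stage), rank(pred)), 0.9)
})
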