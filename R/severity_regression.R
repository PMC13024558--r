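# Stage 2: subject-level continuous Hoehn & Yahr severity prediction with
# gradient-boosted regression, metrics, Cohen's f2 effect size and
# noncentral-F post hoc power.

#' Subject-level feature vectors from windowed tokens
#'
#' Each subject is summarized by the across-window mean and across-window
#' SD (0 for a single window) of each of the 36 raw token features: 72
#' values, invariant to window order.
#'
#' @param tokens `token_dataset` with raw features.
#' @return Data frame: subject_id, label, then 72 feature columns named
#'   `<feature>_wmean` / `<feature>_wstd`.
#' @export
subject_features <- function(tokens) {
  assert_that(nrow(tokens$meta) > 0, "subject_features: no windows")
  sid <- tokens$meta$subject_id
  ids <- sort(unique(sid))
  cnt <- as.vector(table(sid)[ids])
  m <- rowsum(tokens$raw, sid)[ids, , drop = FALSE] / cnt
  sq <- rowsum(tokens$raw^2, sid)[ids, , drop = FALSE] / cnt
  v <- (sq - m^2) * ifelse(cnt > 1, cnt / (cnt - 1), 0)
  v[v < 0] <- 0
  s <- sqrt(v)
  colnames(m) <- paste0(colnames(tokens$raw), "_wmean")
  colnames(s) <- paste0(colnames(tokens$raw), "_wstd")
  lab <- tapply(tokens$meta$label, sid, `[`, 1)[ids]
  out <- data.frame(subject_id = ids, label = as.integer(lab), row.names = NULL)
  cbind(out, as.data.frame(m, row.names = NULL), as.data.frame(s, row.names = NULL))
}

severity_feature_cols <- function(df) {
  setdiff(names(df), c("subject_id", "label", "hy_stage"))
}

#' Train the gradient-boosted severity regressor
#'
#' XGBoost regression (squared-error objective) on subject feature
#' vectors; deterministic given the seed. The training subject ids are
#' recorded so prediction can enforce the subject-wise guard.
#'
#' @param train Data frame from [subject_features()] with an added
#'   `hy_stage` target column.
#' @param config List of booster settings: nrounds (300), max_depth (3),
#'   eta (0.05), subsample (0.9), seed.
#' @return A `severity_model`.
#' @export
train_severity_model <- function(train, config = list()) {
  assert_that(nrow(train) >= 5, "train_severity_model: need >= 5 training subjects")
  assert_that("hy_stage" %in% names(train), "train_severity_model: hy_stage target required")
  cfg <- utils::modifyList(list(nrounds = 300L, max_depth = 3L, eta = 0.05,
                                subsample = 0.9, seed = 1L), config)
  cols <- severity_feature_cols(train)
  X <- as.matrix(train[, cols, drop = FALSE])
  booster <- xgboost::xgboost(
    x = X, y = train$hy_stage,
    nrounds = cfg$nrounds, max_depth = cfg$max_depth, learning_rate = cfg$eta,
    subsample = cfg$subsample, objective = "reg:squarederror",
    nthreads = 1L, seed = cfg$seed, verbosity = 0)
  structure(list(booster = booster, feature_cols = cols,
                 train_subjects = train$subject_id, config = cfg),
            class = "severity_model")
}

#' Predict continuous severity for held-out subjects
#'
#' Aborts if any subject was seen during training (subject-wise guard).
#'
#' @param model A [train_severity_model()] result.
#' @param newdata Subject feature data frame.
#' @param allow_train_subjects Set TRUE only to score training subjects
#'   deliberately.
#' @return Numeric predictions, one per row of `newdata`.
#' @export
predict_severity <- function(model, newdata, allow_train_subjects = FALSE) {
  overlap <- intersect(model$train_subjects, newdata$subject_id)
  if (!allow_train_subjects && length(overlap) > 0) {
    stop_gaitxai("predict_severity: subject(s) %s present in training data (leakage)",
                 paste(overlap, collapse = ", "), class = "gaitxai_leakage_error")
  }
  X <- as.matrix(newdata[, model$feature_cols, drop = FALSE])
  as.numeric(predict(model$booster, X))
}

#' Severity regression metrics
#'
#' MAE, RMSE, R-squared about the mean of the actual values, and
#' tie-corrected Spearman rank correlation with a t-approximation
#' p-value.
#'
#' @param actual,predicted Equal-length numeric vectors (n >= 2).
#' @return List: mae, rmse, r2, spearman_rho, rho_p.
#' @export
regression_metrics <- function(actual, predicted) {
  n <- length(actual)
  assert_that(n == length(predicted) && n >= 2, "regression_metrics: need paired vectors, n >= 2")
  err <- actual - predicted
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  ss_tot <- sum((actual - mean(actual))^2)
  assert_that(ss_tot > 0, "regression_metrics: zero variance in actual values",
              class = "gaitxai_degenerate_error")
  r2 <- 1 - sum(err^2) / ss_tot
  rho <- suppressWarnings(stats::cor(rank(actual), rank(predicted)))
  if (is.na(rho)) {
    rho_p <- NA_real_   # constant predictions: rank correlation undefined
  } else {
    tstat <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
    rho_p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(mae = mae, rmse = rmse, r2 = r2, spearman_rho = rho, rho_p = rho_p)
}

#' Cohen's f-squared from R-squared
#'
#' @param r2 Coefficient of determination in [0, 1).
#' @return `f2 = r2 / (1 - r2)`.
#' @export
effect_size_f2 <- function(r2) {
  assert_that(r2 >= 0 && r2 < 1, "effect_size_f2: r2 must be in [0, 1)")
  r2 / (1 - r2)
}

#' Post hoc power of a regression analysis
#'
#' Power of the overall F test at effect size f2 with `n_predictors`
#' numerator df and `n_subjects - n_predictors - 1` denominator df,
#' using the noncentral F distribution with noncentrality
#' `lambda = f2 * n_subjects` (Cohen's convention).
#'
#' @param f2 Effect size (>= 0).
#' @param n_subjects Sample size.
#' @param n_predictors Number of predictors.
#' @param alpha Significance level.
#' @return Power in [alpha, 1]; exactly alpha at f2 = 0.
#' @export
posthoc_power <- function(f2, n_subjects, n_predictors, alpha = 0.05) {
  assert_that(f2 >= 0, "posthoc_power: f2 must be >= 0")
  assert_that(alpha > 0 && alpha < 1, "posthoc_power: alpha must be in (0, 1)")
  df1 <- n_predictors
  df2 <- n_subjects - n_predictors - 1
  assert_that(df1 >= 1 && df2 >= 1, "posthoc_power: infeasible degrees of freedom")
  fcrit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(fcrit, df1, df2, ncp = f2 * n_subjects, lower.tail = FALSE)
}
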