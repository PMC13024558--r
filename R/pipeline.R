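# End-to-end orchestration: simulate -> window/tokenize -> stage-1
# subject-wise classification across backbones -> stability-consensus
# Integrated-Gradients biomarkers with data-level validation -> stage-2
# continuous severity regression. Config-driven and fully seeded: two
# runs from the same config are identical.

#' Pipeline run configuration
#'
#' @param cohort A [cohort_config()] (synthetic run) or NULL when signals
#'   are supplied directly to the stages.
#' @param window A [window_config()].
#' @param ratios Train/val/test subject fractions.
#' @param n_repeats Number of repeated subject-wise splits.
#' @param base_seed Seed of the first split (split k adds k - 1).
#' @param archs Backbone architectures to run.
#' @param width,dropout Shared model size settings.
#' @param training A [training_config()]; its seed field is re-derived
#'   per (split, arch).
#' @param ig_steps Integrated-Gradients Riemann steps.
#' @param top_fraction Per-experiment top-attribution fraction.
#' @param stability_threshold Consensus stability threshold.
#' @param alpha Significance level for biomarker validation.
#' @param stage2 Booster settings for [train_severity_model()].
#' @param stage2_mode `"inclusive"` evaluates severity on all test
#'   subjects with controls anchored at stage 0; `"classified"` restricts
#'   evaluation to subjects flagged PD-positive by stage 1.
#' @return A `run_config` object.
#' @export
run_config <- function(cohort = cohort_config(), window = window_config(),
                       ratios = c(0.7, 0.15, 0.15), n_repeats = 5L, base_seed = 101L,
                       archs = c("tcn", "bigru_attn", "fcnn_transformer"),
                       width = 32L, dropout = 0.1,
                       training = training_config(),
                       ig_steps = 50L, top_fraction = 0.2, stability_threshold = 0.2,
                       alpha = 0.05, stage2 = list(),
                       stage2_mode = c("inclusive", "classified")) {
  structure(list(cohort = cohort, window = window, ratios = ratios,
                 n_repeats = as.integer(n_repeats), base_seed = as.integer(base_seed),
                 archs = archs, width = as.integer(width), dropout = dropout,
                 training = training, ig_steps = as.integer(ig_steps),
                 top_fraction = top_fraction, stability_threshold = stability_threshold,
                 alpha = alpha, stage2 = stage2,
                 stage2_mode = match.arg(stage2_mode)),
            class = "run_config")
}

#' Stage 1: repeated subject-wise classification across backbones
#'
#' For every (split, architecture) pair: fit channel statistics on the
#' training subjects only, train with weighted BCE and early stopping on
#' validation AUC, evaluate on the held-out subjects, and compute the
#' Integrated-Gradients attribution record on the test windows.
#'
#' @param signals Named list of [gait_signal()] (names = subject ids).
#' @param table A [subject_table()].
#' @param config A [run_config()].
#' @return A `stage1_result`: `experiments` (one entry per (arch, split)
#'   with metrics, attribution record and the trained model), `summary`
#'   (per-arch window-level repeat aggregation), `wilcoxon` (pairwise
#'   paired AUC comparisons), `plans`, and `tokens_ref` (tokenization of
#'   the full cohort used downstream for raw-feature analyses).
#' @export
run_stage1 <- function(signals, table, config = run_config()) {
  plans <- make_repeated_splits(table, config$ratios, config$n_repeats, config$base_seed)
  experiments <- list()
  tokens_ref <- NULL
  for (plan in plans) {
    tk <- tokenize_cohort(signals, table, plan, config$window)
    tokens <- tk$tokens
    if (is.null(tokens_ref)) tokens_ref <- tokens
    assert_no_leakage(plan, tokens)
    part <- unname(plan$assignment[tokens$meta$subject_id])
    subset_tokens <- function(p) {
      keep <- part == p
      structure(list(meta = tokens$meta[keep, , drop = FALSE],
                     features = tokens$features[keep, , drop = FALSE],
                     raw = tokens$raw[keep, , drop = FALSE]), class = "token_dataset")
    }
    tr <- subset_tokens("train"); va <- subset_tokens("val"); te <- subset_tokens("test")
    for (arch in config$archs) {
      seed <- derive_seed(plan$seed, paste0("train_", arch))
      spec <- model_spec(arch, width = config$width, dropout = config$dropout)
      model <- build_model(spec, init_seed = seed)
      tcfg <- config$training
      tcfg$seed <- seed
      model <- train_classifier(model, tr, va, tcfg)
      probs <- predict_proba(model, te)
      win_metrics <- compute_metrics(probs, te$meta$label, level = "window")
      subj <- subject_level(probs, te$meta$subject_id, te$meta$label)
      subj_metrics <- compute_metrics(subj$probability, subj$label, level = "subject")
      attribution <- aggregate_attributions(model, te, n_steps = config$ig_steps)
      experiments[[paste0(arch, "_seed", plan$seed)]] <- list(
        arch = arch, split_seed = plan$seed, model = model,
        window_metrics = win_metrics, subject_metrics = subj_metrics,
        subject_predictions = subj, attribution = attribution,
        test_subjects = names(plan$assignment)[plan$assignment == "test"])
    }
  }
  summary <- lapply(stats::setNames(config$archs, config$archs), function(a) {
    ms <- lapply(Filter(function(e) e$arch == a, experiments), `[[`, "window_metrics")
    if (length(ms) >= 2) aggregate_repeats(ms, seed = config$base_seed) else NULL
  })
  wilcoxon <- list()
  if (length(config$archs) >= 2 && config$n_repeats >= 2) {
    aucs <- sapply(stats::setNames(config$archs, config$archs), function(a) {
      vapply(Filter(function(e) e$arch == a, experiments),
             function(e) e$window_metrics$auc, numeric(1))
    })
    pairs <- utils::combn(config$archs, 2, simplify = FALSE)
    for (pr in pairs) {
      wilcoxon[[paste(pr, collapse = "_vs_")]] <- paired_wilcoxon(aucs[, pr[1]], aucs[, pr[2]])
    }
  }
  structure(list(experiments = experiments, summary = summary, wilcoxon = wilcoxon,
                 plans = plans, tokens_ref = tokens_ref, config = config),
            class = "stage1_result")
}

#' Stage XAI: stability consensus and data-level biomarker validation
#'
#' Pools the per-experiment top-attribution sets (n_experiments =
#' n_splits x n_models), scores stability, thresholds the consensus set,
#' and validates each consensus feature on raw window features
#' (Mann-Whitney, Cliff's delta PD - CO, BH-FDR within the consensus
#' family).
#'
#' @param stage1 A [run_stage1()] result.
#' @param config Defaults to the stage-1 config.
#' @return A `xai_result`: `stability` table, `consensus` subset and
#'   `biomarkers` validation table (zero-row, with a warning, when no
#'   feature reaches the threshold).
#' @export
run_xai <- function(stage1, config = stage1$config) {
  subsets <- lapply(stage1$experiments,
                    function(e) top_fraction_features(e$attribution, config$top_fraction))
  stability <- stability_scores(unname(subsets))
  consensus <- consensus_features(stability, config$stability_threshold)
  if (nrow(consensus) == 0) {
    warning("no consensus features at the stability threshold; empty validation table")
    biomarkers <- biomarker_validation(stage1$tokens_ref,
                                       features = character(0))[0, ]
  } else {
    biomarkers <- biomarker_validation(stage1$tokens_ref, features = consensus$feature)
  }
  structure(list(stability = stability, consensus = consensus,
                 biomarkers = biomarkers, alpha = config$alpha),
            class = "xai_result")
}

#' Stage 2: continuous severity regression
#'
#' Subject-level feature vectors (across-window mean and SD of the raw
#' token features) predict continuous Hoehn & Yahr stage with gradient
#' boosting. For each stage-1 split, the model trains on the train+val
#' subjects and predicts the held-out test subjects; per-subject
#' predictions are averaged over the splits in which the subject was
#' held out, so every reported prediction is out-of-sample.
#'
#' @param stage1 A [run_stage1()] result.
#' @param table The [subject_table()] with `hy_stage`.
#' @param config Defaults to the stage-1 config.
#' @return A `severity_report`: per-subject (actual, predicted) data
#'   frame, metrics (mae, rmse, r2, spearman_rho, rho_p), f2 and post hoc
#'   power at `alpha`.
#' @export
run_stage2 <- function(stage1, table, config = stage1$config) {
  feats <- subject_features(stage1$tokens_ref)
  feats$hy_stage <- table$hy_stage[match(feats$subject_id, table$subject_id)]
  preds <- list()
  for (plan in stage1$plans) {
    train_ids <- names(plan$assignment)[plan$assignment != "test"]
    test_ids <- names(plan$assignment)[plan$assignment == "test"]
    tr <- feats[feats$subject_id %in% train_ids, , drop = FALSE]
    te <- feats[feats$subject_id %in% test_ids, , drop = FALSE]
    cfg <- utils::modifyList(config$stage2, list(seed = derive_seed(plan$seed, "stage2")))
    fit <- train_severity_model(tr, cfg)
    p <- predict_severity(fit, te)
    preds[[length(preds) + 1L]] <- data.frame(subject_id = te$subject_id,
                                              actual = te$hy_stage, predicted = p)
  }
  pooled <- do.call(rbind, preds)
  per_subject <- stats::aggregate(cbind(actual, predicted) ~ subject_id, pooled, mean)
  if (config$stage2_mode == "classified") {
    pos <- stage1_positive_subjects(stage1)
    per_subject <- per_subject[per_subject$subject_id %in% pos, , drop = FALSE]
  }
  metrics <- regression_metrics(per_subject$actual, per_subject$predicted)
  f2 <- effect_size_f2(max(0, metrics$r2))
  n_pred <- length(severity_feature_cols(feats))
  power <- if (nrow(per_subject) > n_pred + 1) {
    posthoc_power(f2, nrow(per_subject), n_pred, config$alpha)
  } else NA_real_
  structure(list(per_subject = per_subject, metrics = metrics, f2 = f2,
                 power = power, n_subjects = nrow(per_subject),
                 n_predictors = n_pred, mode = config$stage2_mode),
            class = "severity_report")
}

# subjects whose stage-1 held-out mean probability calls them PD
stage1_positive_subjects <- function(stage1, threshold = 0.5) {
  sp <- do.call(rbind, lapply(stage1$experiments, `[[`, "subject_predictions"))
  agg <- stats::aggregate(probability ~ subject_id, sp, mean)
  agg$subject_id[agg$probability >= threshold]
}

#' Run the full two-stage pipeline on a synthetic cohort
#'
#' @param config A [run_config()] with a `cohort` entry.
#' @return List with `cohort` (truth retained), `stage1`, `xai`,
#'   `stage2` and the `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  assert_that(!is.null(config$cohort), "run_pipeline: config must carry a cohort_config")
  cohort <- generate_cohort(config$cohort)
  stage1 <- run_stage1(cohort$signals, cohort$table, config)
  xai <- run_xai(stage1, config)
  stage2 <- run_stage2(stage1, cohort$table, config)
  list(cohort = cohort, stage1 = stage1, xai = xai, stage2 = stage2, config = config)
}

#' @export
print.severity_report <- function(x, ...) {
  cat(sprintf(paste0("<severity_report> n=%d subjects (%s mode)\n",
                     "  MAE=%.3f RMSE=%.3f R2=%.3f Spearman rho=%.3f (p=%.2g)\n",
                     "  f2=%.2f power=%s\n"),
              x$n_subjects, x$mode, x$metrics$mae, x$metrics$rmse, x$metrics$r2,
              x$metrics$spearman_rho, x$metrics$rho_p, x$f2,
              ifelse(is.na(x$power), "NA (n <= predictors + 1)", sprintf("%.3f", x$power))))
  invisible(x)
}
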