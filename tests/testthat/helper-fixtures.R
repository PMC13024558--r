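# Shared fixtures, all generated in code at test time.

# Small synthetic cohort; short records keep the suite fast.
small_cohort <- function(n_co = 10, n_pd = 10, seconds = 12, seed = 42, ...) {
  generate_cohort(cohort_config(n_control = n_co, n_pd = n_pd,
                                record_seconds = seconds, seed = seed, ...))
}

# Linearly separable two-blob token dataset: class 1 windows are shifted
# along a handful of std features. `n_subj` subjects per class,
# `n_win` windows each.
blob_tokens <- function(n_subj = 12, n_win = 12, shift = 3, seed = 1,
                        signal_features = c("sensor_1_std", "sensor_9_std")) {
  set.seed(seed)
  fn <- feature_names()
  n <- 2 * n_subj * n_win
  feat <- matrix(rnorm(n * 36, sd = 0.7), n, 36, dimnames = list(NULL, fn))
  sid <- rep(sprintf("S%03d", seq_len(2 * n_subj)), each = n_win)
  label <- rep(c(0L, 1L), each = n_subj * n_win)
  feat[label == 1, signal_features] <- feat[label == 1, signal_features] + shift
  structure(list(meta = data.frame(subject_id = sid, label = label),
                 features = feat,
                 raw = feat * 50 + 100),   # raw-scale copy for biomarker paths
            class = "token_dataset")
}

split_blob <- function(tokens, frac_train = 0.6, frac_val = 0.2, seed = 3) {
  ids <- unique(tokens$meta$subject_id)
  labs <- tapply(tokens$meta$label, tokens$meta$subject_id, `[`, 1)[ids]
  set.seed(seed)
  part <- character(length(ids)); names(part) <- ids
  for (g in 0:1) {
    gids <- sample(ids[labs == g])
    k <- length(gids)
    ntr <- round(frac_train * k); nva <- round(frac_val * k)
    part[gids] <- rep(c("train", "val", "test"), c(ntr, nva, k - ntr - nva))
  }
  take <- function(p) {
    keep <- part[tokens$meta$subject_id] == p
    structure(list(meta = tokens$meta[keep, , drop = FALSE],
                   features = tokens$features[keep, , drop = FALSE],
                   raw = tokens$raw[keep, , drop = FALSE]), class = "token_dataset")
  }
  list(train = take("train"), val = take("val"), test = take("test"))
}

# A hand-built linear "backbone": logit = sum(w * x) over the 18 x 2 input.
# Satisfies the gait_model forward contract, so IG has a closed form.
linear_gait_model <- function(w = NULL, seed = 5) {
  if (is.null(w)) w <- with_seed_local(seed, matrix(rnorm(36), 36, 1))
  structure(list(
    spec = structure(list(arch = "linear", width = 1L, depth = 1L, dropout = 0),
                     class = "model_spec"),
    params = list(W = w),
    forward = function(pn, x, spec, training) {
      d <- dim(x$value)
      gaitxai:::ad_matmul(gaitxai:::ad_reshape(
        gaitxai:::ad_perm23(x), c(d[1], d[2] * d[3])), pn$W)
    },
    n_params = 36), class = "gait_model")
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Quick trained tiny model on the blob fixture (cached per arch per session).
trained_blob_model <- local({
  cache <- list()
  function(arch, width = 8, seed = 11) {
    key <- paste(arch, width, seed)
    if (!is.null(cache[[key]])) return(cache[[key]])
    tk <- blob_tokens(seed = seed)
    sp <- split_blob(tk)
    model <- build_model(model_spec(arch, width = width, dropout = 0), init_seed = seed)
    model <- train_classifier(model, sp$train, sp$val,
                              training_config(learning_rate = 5e-3, batch_size = 48,
                                              max_epochs = 60, patience = 10, seed = seed))
    res <- list(model = model, splits = sp)
    cache[[key]] <<- res
    res
  }
})
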