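# Fixed-length overlapping windowing, z-score normalization with
# training-cohort channel statistics, and the 18-token x 2-feature
# (mean, std) window representation with subject provenance.

#' Windowing configuration
#'
#' @param window_len Window length in samples (100 => 1 s at 100 Hz).
#' @param overlap Overlap fraction in [0, 1); 0.5 halves the step.
#' @param epsilon Floor below which a channel SD is treated as degenerate
#'   (replaced by 1 so constant channels normalize to 0).
#' @return A `window_config` object.
#' @export
window_config <- function(window_len = 100L, overlap = 0.5, epsilon = 1e-8) {
  assert_that(window_len >= 2, "window_config: window_len must be >= 2")
  assert_that(overlap >= 0 && overlap < 1, "window_config: overlap must be in [0, 1)")
  assert_that(epsilon > 0, "window_config: epsilon must be positive")
  structure(list(window_len = as.integer(window_len), overlap = overlap,
                 epsilon = epsilon), class = "window_config")
}

#' Token/feature names of the window representation
#'
#' 18 tokens (sensors 1-8 left, 9-16 right, left/right total force), two
#' features per token. The returned order is the canonical column order
#' used throughout (token-major: `sensor_1_mean`, `sensor_1_std`, ...).
#'
#' @return Character vector of length 36.
#' @export
feature_names <- function() {
  tokens <- token_names()
  as.vector(t(outer(tokens, c("mean", "std"), paste, sep = "_")))
}

token_names <- function() c(paste0("sensor_", 1:16), "total_l", "total_r")

#' Segment a record into fixed-length overlapping windows
#'
#' Step is `window_len * (1 - overlap)` rounded to the nearest integer
#' (minimum 1); the trailing partial window is discarded.
#'
#' @param signal A [gait_signal()].
#' @param config A [window_config()].
#' @return Data frame with columns `start`, `end` (1-based, inclusive);
#'   zero rows, with a `gaitxai_record_too_short` warning, when the record
#'   is shorter than one window.
#' @export
segment_windows <- function(signal, config) {
  T <- nrow(signal$channels)
  L <- config$window_len
  if (T < L) {
    warning(warningCondition(
      sprintf("record %s too short for one window (%d < %d samples)", signal$subject_id, T, L),
      class = "gaitxai_record_too_short"))
    return(data.frame(start = integer(0), end = integer(0)))
  }
  step <- max(1L, as.integer(round(L * (1 - config$overlap))))
  starts <- seq(1L, T - L + 1L, by = step)
  data.frame(start = starts, end = starts + L - 1L)
}

#' Fit per-channel normalization statistics on training signals
#'
#' Mean and SD per channel over all samples of the supplied (training)
#' subjects; SDs below `epsilon` are replaced by 1. The subject ids that
#' contributed are recorded so downstream code can verify that no
#' validation or test subject leaked into the normalization.
#'
#' @param signals List of [gait_signal()] from training subjects only.
#' @param epsilon SD floor.
#' @return A `channel_stats` object with `mean` and `sd` (length 18).
#' @export
fit_channel_stats <- function(signals, epsilon = 1e-8) {
  assert_that(length(signals) > 0, "fit_channel_stats: empty training set")
  n <- 0; s1 <- numeric(18L); s2 <- numeric(18L)
  for (sig in signals) {
    n <- n + nrow(sig$channels)
    s1 <- s1 + colSums(sig$channels)
    s2 <- s2 + colSums(sig$channels^2)
  }
  mu <- s1 / n
  sd <- sqrt(pmax(0, (s2 - n * mu^2) / (n - 1)))
  sd[sd < epsilon] <- 1
  structure(list(mean = mu, sd = sd,
                 subject_ids = vapply(signals, function(s) s$subject_id, character(1))),
            class = "channel_stats")
}

# window sums via cumulative sums: O(1) per window and channel
window_moments <- function(channels, windows) {
  L <- windows$end[1] - windows$start[1] + 1L
  cs1 <- apply(channels, 2L, cumsum)
  cs2 <- apply(channels^2, 2L, cumsum)
  z <- matrix(0, 1L, ncol(channels))
  cs1 <- rbind(z, cs1); cs2 <- rbind(z, cs2)
  sums <- cs1[windows$end + 1L, , drop = FALSE] - cs1[windows$start, , drop = FALSE]
  sqs <- cs2[windows$end + 1L, , drop = FALSE] - cs2[windows$start, , drop = FALSE]
  m <- sums / L
  v <- (sqs - L * m^2) / (L - 1)
  v[v < 0] <- 0
  list(mean = m, sd = sqrt(v))
}

#' Tokenize a record's windows into the 18 x 2 representation
#'
#' Features are computed on the z-scored signal (window mean of channel c
#' becomes `(mean - mu_c) / sd_c`, window SD becomes `sd / sd_c`);
#' `raw` carries the same quantities on the unnormalized signal for
#' data-level biomarker statistics. The subject identifier is carried on
#' every window.
#'
#' @param signal A [gait_signal()].
#' @param windows Output of [segment_windows()].
#' @param stats A [fit_channel_stats()] result.
#' @param label 0 for control, 1 for PD.
#' @return A `token_dataset`: list with `meta` (subject_id, label),
#'   `features` (n x 36 normalized matrix) and `raw` (n x 36 raw matrix).
#' @export
tokenize_windows <- function(signal, windows, stats, label) {
  nw <- nrow(windows)
  fn <- feature_names()
  if (nw == 0) {
    return(structure(list(
      meta = data.frame(subject_id = character(0), label = integer(0)),
      features = matrix(0, 0, 36L, dimnames = list(NULL, fn)),
      raw = matrix(0, 0, 36L, dimnames = list(NULL, fn))), class = "token_dataset"))
  }
  mo <- window_moments(signal$channels, windows)
  raw <- matrix(0, nw, 36L, dimnames = list(NULL, fn))
  norm <- matrix(0, nw, 36L, dimnames = list(NULL, fn))
  raw[, seq(1, 36, by = 2)] <- mo$mean
  raw[, seq(2, 36, by = 2)] <- mo$sd
  norm[, seq(1, 36, by = 2)] <- sweep(sweep(mo$mean, 2L, stats$mean, "-"), 2L, stats$sd, "/")
  norm[, seq(2, 36, by = 2)] <- sweep(mo$sd, 2L, stats$sd, "/")
  structure(list(
    meta = data.frame(subject_id = rep(signal$subject_id, nw),
                      label = rep(as.integer(label), nw)),
    features = norm, raw = raw), class = "token_dataset")
}

#' Combine token datasets from several records
#'
#' @param datasets List of `token_dataset` objects.
#' @return A single `token_dataset`.
#' @export
bind_tokens <- function(datasets) {
  datasets <- Filter(function(d) nrow(d$meta) > 0, datasets)
  assert_that(length(datasets) > 0, "bind_tokens: no windows to combine")
  structure(list(meta = do.call(rbind, lapply(datasets, `[[`, "meta")),
                 features = do.call(rbind, lapply(datasets, `[[`, "features")),
                 raw = do.call(rbind, lapply(datasets, `[[`, "raw"))),
            class = "token_dataset")
}

#' @export
print.token_dataset <- function(x, ...) {
  cat(sprintf("<token_dataset> %d windows, %d subjects (%d PD windows)\n",
              nrow(x$meta), length(unique(x$meta$subject_id)), sum(x$meta$label == 1)))
  invisible(x)
}

#' Flat data-frame export of a token dataset
#'
#' @param ds A `token_dataset`.
#' @param which `"features"` (normalized, model input) or `"raw"`.
#' @return Data frame with subject_id, label and 36 feature columns.
#' @export
tokens_as_data_frame <- function(ds, which = c("features", "raw")) {
  which <- match.arg(which)
  cbind(ds$meta, as.data.frame(ds[[which]]))
}

# (n, 18, 2) model input array from normalized features.
tokens_to_array <- function(ds) {
  n <- nrow(ds$features)
  arr <- array(0, dim = c(n, 18L, 2L))
  arr[, , 1] <- ds$features[, seq(1, 36, by = 2)]
  arr[, , 2] <- ds$features[, seq(2, 36, by = 2)]
  arr
}

# Tokenize a full cohort against one split plan: channel stats are fitted
# on the plan's training subjects only.
tokenize_cohort <- function(signals, table, plan, wcfg) {
  labels <- stats::setNames(ifelse(table$group == "PD", 1L, 0L), table$subject_id)
  train_ids <- names(plan$assignment)[plan$assignment == "train"]
  stats <- fit_channel_stats(signals[train_ids], wcfg$epsilon)
  ds <- lapply(signals, function(sig) {
    tokenize_windows(sig, suppressWarnings(segment_windows(sig, wcfg)),
                     stats, labels[[sig$subject_id]])
  })
  list(tokens = bind_tokens(ds), stats = stats)
}
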