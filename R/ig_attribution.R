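# Integrated Gradients attribution over the 18 x 2 window features for
# any trained backbone. The attribution target is the predicted PD
# probability; the path integral is approximated with a right-Riemann sum,
#   IG_i = (x_i - x'_i) * (1/m) * sum_{k=1..m} dF(x' + (k/m)(x - x'))/dx_i,
# which is exact for linear models at any step count and satisfies
# completeness (sum IG -> F(x) - F(baseline)) as m grows.

# Vectorized core: all m path points of a chunk of windows go through the
# network as one batch.
ig_batch <- function(model, X, baseline, m, target = "probability") {
  nw <- dim(X)[1]
  alphas <- seq_len(m) / m
  xs <- array(0, dim = c(nw * m, 18L, 2L))
  for (w in seq_len(nw)) {
    dwin <- X[w, , ] - baseline
    for (k in seq_len(m)) {
      xs[(w - 1L) * m + k, , ] <- baseline + alphas[k] * dwin
    }
  }
  fw <- model_forward(model, xs, training = FALSE)
  out_node <- if (target == "probability") ad_sigmoid(fw$logit) else fw$logit
  ad_backward(out_node, seed = matrix(1, nw * m, 1))
  g <- fw$x$grad
  assert_that(all(is.finite(g)), "integrated_gradients: non-finite gradients")
  fb <- model_forward(model, array(baseline, dim = c(1L, 18L, 2L)), training = FALSE)
  f_base <- as.numeric(fb$logit$value)
  if (target == "probability") f_base <- 1 / (1 + exp(-f_base))
  lapply(seq_len(nw), function(w) {
    rows <- (w - 1L) * m + seq_len(m)
    avg_grad <- apply(g[rows, , , drop = FALSE], c(2, 3), mean)
    diffw <- matrix(X[w, , ] - baseline, 18L, 2L)
    ig <- diffw * avg_grad
    f_x <- out_node$value[rows[m], 1]
    list(attributions = ig,
         completeness_gap = abs(sum(ig) - (f_x - f_base)),
         f_x = f_x, f_baseline = f_base)
  })
}

#' Integrated Gradients for one window
#'
#' @param model Trained [build_model()] result.
#' @param x 18 x 2 feature matrix (normalized window representation).
#' @param baseline Same-shape baseline; the default all-zero baseline is
#'   the training-cohort channel mean in normalized space.
#' @param n_steps Riemann steps `m`.
#' @return List with `attributions` (18 x 2), `completeness_gap`
#'   (|sum IG - (F(x) - F(baseline))|) and the two endpoint outputs
#'   `f_x`, `f_baseline`.
#' @export
integrated_gradients <- function(model, x, baseline = NULL, n_steps = 50L,
                                 target = c("probability", "output")) {
  target <- match.arg(target)
  x <- as.matrix(x)
  assert_that(all(dim(x) == c(18L, 2L)), "integrated_gradients: x must be 18 x 2")
  baseline <- if (is.null(baseline)) matrix(0, 18L, 2L) else as.matrix(baseline)
  assert_that(all(dim(baseline) == dim(x)), "integrated_gradients: baseline shape mismatch")
  m <- as.integer(n_steps)
  assert_that(m >= 1, "integrated_gradients: n_steps must be >= 1")
  ig_batch(model, array(x, dim = c(1L, 18L, 2L)), baseline, m,
           if (target == "output") "output" else "probability")[[1]]
}

#' Aggregate attributions over a test set
#'
#' Per-feature mean of |IG| over all test windows (magnitude ranking), with
#' signed means exported alongside for inspection.
#'
#' @param model Trained model.
#' @param tokens `token_dataset` of test windows (or an (n, 18, 2) array).
#' @param baseline Shared baseline (default all zeros).
#' @param n_steps Riemann steps per window.
#' @return An `attribution_record`: data frame with `feature`,
#'   `aggregate` (mean |IG|, non-negative) and `signed_mean`, one row per
#'   feature in canonical order. The largest per-window completeness gap
#'   is attached as attribute `max_completeness_gap`.
#' @export
aggregate_attributions <- function(model, tokens, baseline = NULL, n_steps = 50L) {
  x <- if (inherits(tokens, "token_dataset")) tokens_to_array(tokens) else tokens
  n <- dim(x)[1]
  assert_that(n >= 1, "aggregate_attributions: empty test set")
  baseline <- if (is.null(baseline)) matrix(0, 18L, 2L) else as.matrix(baseline)
  m <- as.integer(n_steps)
  chunk <- max(1L, 512L %/% m)
  acc_abs <- matrix(0, 18L, 2L)
  acc_sgn <- matrix(0, 18L, 2L)
  max_gap <- 0
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    res <- ig_batch(model, x[rows, , , drop = FALSE], baseline, m)
    for (r in res) {
      acc_abs <- acc_abs + abs(r$attributions)
      acc_sgn <- acc_sgn + r$attributions
      max_gap <- max(max_gap, r$completeness_gap)
    }
  }
  # token-major flattening matches feature_names(): rows are tokens
  flat <- function(mm) as.vector(t(mm))
  rec <- data.frame(feature = feature_names(),
                    aggregate = flat(acc_abs) / n,
                    signed_mean = flat(acc_sgn) / n,
                    stringsAsFactors = FALSE)
  attr(rec, "max_completeness_gap") <- max_gap
  class(rec) <- c("attribution_record", "data.frame")
  rec
}
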