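# Three small sequence classifiers over the 18-token x 2-feature window
# representation, built on the reverse-mode autodiff core. All three share
# one I/O contract: input (B, 18, 2) array -> logit (B, 1); probabilities are
# sigmoid(logit). The 18-token axis is treated as the sequence dimension.

#' Model specification for a gait-window classifier
#'
#' @param arch One of `"tcn"` (dilated causal temporal convolutional
#'   network), `"bigru_attn"` (bidirectional GRU with additive attention
#'   pooling) or `"fcnn_transformer"` (per-token embedding with
#'   self-attention encoder layers).
#' @param width Hidden width (channels / GRU units / embedding dim).
#' @param depth Number of TCN blocks or transformer encoder layers
#'   (defaults: 3 for TCN, 1 for BiGRU, 2 for transformer).
#' @param dropout Dropout probability applied during training.
#' @param heads Attention heads (transformer only); must divide `width`.
#' @return An object of class `model_spec`.
#' @examples
#' spec <- model_spec("tcn", width = 16)
#' model <- build_model(spec, init_seed = 1)
#' @export
model_spec <- function(arch = c("tcn", "bigru_attn", "fcnn_transformer"),
                       width = 32L, depth = NULL, dropout = 0.1, heads = 4L) {
  arch <- match.arg(arch)
  depth <- as.integer(depth %||% switch(arch, tcn = 3L, bigru_attn = 1L, fcnn_transformer = 2L))
  width <- as.integer(width)
  assert_that(width > 0 && depth > 0, "model_spec: width and depth must be positive")
  assert_that(dropout >= 0 && dropout < 1, "model_spec: dropout must be in [0,1)")
  if (arch == "fcnn_transformer") {
    assert_that(width %% heads == 0, "model_spec: heads must divide width")
  }
  structure(list(arch = arch, width = width, depth = depth,
                 dropout = dropout, heads = as.integer(heads)),
            class = "model_spec")
}

glorot <- function(nin, nout) {
  matrix(stats::runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nin, nout)
}

init_params <- function(spec, n_tokens = 18L, n_feat = 2L) {
  w <- spec$width
  p <- list()
  if (spec$arch == "tcn") {
    cin <- n_feat
    for (l in seq_len(spec$depth)) {
      p[[paste0("W0_", l)]] <- glorot(cin, w)
      p[[paste0("W1_", l)]] <- glorot(cin, w)
      p[[paste0("W2_", l)]] <- glorot(cin, w)
      p[[paste0("b_", l)]] <- numeric(w)
      if (cin != w) p[[paste0("Wres_", l)]] <- glorot(cin, w)
      cin <- w
    }
    p$Whead <- glorot(w, 1L); p$bhead <- numeric(1L)
  } else if (spec$arch == "bigru_attn") {
    for (dir in c("f", "b")) {
      # gate order [z | r | n]; input projection carries no separate bias
      p[[paste0("Wx_", dir)]] <- glorot(n_feat, 3L * w)
      p[[paste0("U_", dir)]] <- glorot(w, 3L * w)
      p[[paste0("b_", dir)]] <- numeric(3L * w)
    }
    p$Wattn <- glorot(2L * w, w); p$battn <- numeric(w)
    p$vattn <- glorot(w, 1L)
    p$Whead <- glorot(2L * w, 1L); p$bhead <- numeric(1L)
  } else {
    p$Wemb <- glorot(n_feat, w); p$bemb <- numeric(w)
    for (l in seq_len(spec$depth)) {
      p[[paste0("Wq_", l)]] <- glorot(w, w)
      p[[paste0("Wk_", l)]] <- glorot(w, w)
      p[[paste0("Wv_", l)]] <- glorot(w, w)
      p[[paste0("Wo_", l)]] <- glorot(w, w); p[[paste0("bo_", l)]] <- numeric(w)
      p[[paste0("g1_", l)]] <- rep(1, w); p[[paste0("be1_", l)]] <- numeric(w)
      p[[paste0("Wf1_", l)]] <- glorot(w, 2L * w); p[[paste0("bf1_", l)]] <- numeric(2L * w)
      p[[paste0("Wf2_", l)]] <- glorot(2L * w, w); p[[paste0("bf2_", l)]] <- numeric(w)
      p[[paste0("g2_", l)]] <- rep(1, w); p[[paste0("be2_", l)]] <- numeric(w)
    }
    p$Whead1 <- glorot(w, w); p$bhead1 <- numeric(w)
    p$Whead2 <- glorot(w, 1L); p$bhead2 <- numeric(1L)
  }
  p
}

# Wrap plain parameter arrays as leaf autodiff nodes.
wrap_params <- function(params) lapply(params, ad_node)

# fold/unfold between (B,T,C) and (B*T,C); valid because R arrays are
# column-major and the leading two dims fold contiguously.
fold2 <- function(x3) {
  d <- dim(x3$value)
  ad_reshape(x3, c(d[1] * d[2], d[3]))
}
unfold3 <- function(x2, B, T) {
  d <- dim(x2$value)
  ad_reshape(x2, c(B, T, d[2]))
}

tok_matmul <- function(x3, W) {
  d <- dim(x3$value)
  unfold3(ad_matmul(fold2(x3), W), d[1], d[2])
}

forward_tcn <- function(pn, x, spec, training) {
  h <- x
  B <- dim(x$value)[1]; T <- dim(x$value)[2]
  for (l in seq_len(spec$depth)) {
    dil <- 2^(l - 1)
    z <- ad_matmul(fold2(h), pn[[paste0("W0_", l)]])
    z <- ad_add(z, ad_matmul(fold2(ad_shift_time(h, dil)), pn[[paste0("W1_", l)]]))
    z <- ad_add(z, ad_matmul(fold2(ad_shift_time(h, 2L * dil)), pn[[paste0("W2_", l)]]))
    z <- ad_add(z, pn[[paste0("b_", l)]])
    y <- ad_dropout(unfold3(ad_relu(z), B, T), spec$dropout, training)
    res <- if (!is.null(pn[[paste0("Wres_", l)]])) tok_matmul(h, pn[[paste0("Wres_", l)]]) else h
    h <- ad_add(y, res)
  }
  pooled <- ad_mean_time_folded(fold2(h), B, T)
  ad_add(ad_matmul(pooled, pn$Whead), pn$bhead)
}

gru_direction <- function(pn, xp3, spec, dir, times) {
  B <- dim(xp3$value)[1]; w <- spec$width
  h <- ad_node(matrix(0, B, w))
  U <- pn[[paste0("U_", dir)]]; b <- pn[[paste0("b_", dir)]]
  outs <- vector("list", length(times))
  for (i in seq_along(times)) {
    h <- ad_gru_step(ad_slice_time(xp3, times[i]), h, U, b)
    outs[[i]] <- h
  }
  outs[order(times)]  # forward time order
}

forward_bigru <- function(pn, x, spec, training) {
  d0 <- dim(x$value); B <- d0[1]; T <- d0[2]
  x2 <- fold2(x)
  xp_f <- unfold3(ad_matmul(x2, pn$Wx_f), B, T)
  xp_b <- unfold3(ad_matmul(x2, pn$Wx_b), B, T)
  fw <- gru_direction(pn, xp_f, spec, "f", seq_len(T))
  bw <- gru_direction(pn, xp_b, spec, "b", rev(seq_len(T)))
  H <- ad_concat_last(ad_stack_time(fw), ad_stack_time(bw))  # (B,T,2w)
  H <- ad_dropout(H, spec$dropout, training)
  e <- ad_matmul(ad_tanh(ad_add(ad_matmul(fold2(H), pn$Wattn), pn$battn)), pn$vattn)
  alpha <- ad_softmax_rows(ad_reshape(e, c(B, T)))
  ctx <- ad_attn_pool(alpha, H)                              # (B,2w)
  ad_add(ad_matmul(ctx, pn$Whead), pn$bhead)
}

forward_transformer <- function(pn, x, spec, training) {
  d0 <- dim(x$value); B <- d0[1]; T <- d0[2]
  h2 <- ad_add(ad_matmul(fold2(x), pn$Wemb), pn$bemb)        # folded (B*T, w)
  for (l in seq_len(spec$depth)) {
    hn <- ad_layernorm(h2, pn[[paste0("g1_", l)]], pn[[paste0("be1_", l)]])
    Q <- unfold3(ad_matmul(hn, pn[[paste0("Wq_", l)]]), B, T)
    K <- unfold3(ad_matmul(hn, pn[[paste0("Wk_", l)]]), B, T)
    V <- unfold3(ad_matmul(hn, pn[[paste0("Wv_", l)]]), B, T)
    mh <- fold2(ad_mha(Q, K, V, spec$heads))
    ao <- ad_dropout(ad_add(ad_matmul(mh, pn[[paste0("Wo_", l)]]), pn[[paste0("bo_", l)]]),
                     spec$dropout, training)
    h2 <- ad_add(h2, ao)
    hn2 <- ad_layernorm(h2, pn[[paste0("g2_", l)]], pn[[paste0("be2_", l)]])
    ff <- ad_add(ad_matmul(ad_relu(ad_add(ad_matmul(hn2, pn[[paste0("Wf1_", l)]]),
                                          pn[[paste0("bf1_", l)]])),
                           pn[[paste0("Wf2_", l)]]), pn[[paste0("bf2_", l)]])
    ff <- ad_dropout(ff, spec$dropout, training)
    h2 <- ad_add(h2, ff)
  }
  pooled <- ad_mean_time_folded(h2, B, T)
  head1 <- ad_relu(ad_add(ad_matmul(pooled, pn$Whead1), pn$bhead1))
  ad_add(ad_matmul(head1, pn$Whead2), pn$bhead2)
}

#' Build an untrained gait-window classifier
#'
#' @param spec A [model_spec()].
#' @param init_seed Integer seed for parameter initialization; two builds
#'   with the same seed are identical.
#' @return A `gait_model` with elements `spec`, `params` (named list of
#'   arrays), `forward` (autodiff forward pass to a logit) and `n_params`.
#' @export
build_model <- function(spec, init_seed = 1L) {
  if (!inherits(spec, "model_spec")) stop_gaitxai("build_model: unknown architecture or invalid spec")
  params <- with_seed(init_seed, init_params(spec))
  fwd <- switch(spec$arch,
                tcn = forward_tcn,
                bigru_attn = forward_bigru,
                fcnn_transformer = forward_transformer)
  structure(list(spec = spec, params = params, forward = fwd,
                 n_params = sum(vapply(params, length, numeric(1)))),
            class = "gait_model")
}

#' @export
print.gait_model <- function(x, ...) {
  cat(sprintf("<gait_model> arch=%s width=%d depth=%d parameters=%d%s\n",
              x$spec$arch, x$spec$width, x$spec$depth, x$n_params,
              if (!is.null(x$best_epoch)) sprintf(" (trained, best epoch %d)", x$best_epoch) else ""))
  invisible(x)
}

# Forward pass on a plain (B,18,2) array; returns list(logit_node, x_node, params).
model_forward <- function(model, x_array, training = FALSE, params = NULL) {
  stopifnot(length(dim(x_array)) == 3L)
  pn <- wrap_params(params %||% model$params)
  xn <- ad_node(x_array)
  logit <- model$forward(pn, xn, model$spec, training)
  list(logit = logit, x = xn, params = pn)
}
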