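# Minimal reverse-mode automatic differentiation on numeric arrays.
#
# This is the differentiable core behind the sequence classifiers and the
# Integrated Gradients attribution: a define-by-run tape of array ops with
# hand-written vector-Jacobian products. Values are base-R numeric vectors,
# matrices or 3-d arrays (batch-first). Nodes are environments created in
# strictly increasing id order, so reverse-id order is a valid topological
# order for backpropagation.

.ad_state <- new.env(parent = emptyenv())
.ad_state$counter <- 0L

ad_node <- function(value, parents = list(), backward = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$backward <- backward
  e$grad <- NULL
  .ad_state$counter <- .ad_state$counter + 1L
  e$id <- .ad_state$counter
  class(e) <- "ad_node"
  e
}

#' @keywords internal
ad_value <- function(x) if (inherits(x, "ad_node")) x$value else x

ad_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Backpropagate from `root`. `seed` defaults to an array of ones with the
# shape of root$value (sum-of-outputs gradient).
ad_backward <- function(root, seed = NULL) {
  if (is.null(seed)) {
    seed <- array(1, dim = if (is.null(dim(root$value))) length(root$value) else dim(root$value))
    if (is.null(dim(root$value))) seed <- as.numeric(seed)
  }
  root$grad <- seed
  # collect reachable nodes
  seen <- new.env(parent = emptyenv())
  stack <- list(root)
  nodes <- list()
  while (length(stack) > 0) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- n
    for (p in n$parents) stack[[length(stack) + 1L]] <- p
  }
  ids <- vapply(nodes, function(n) n$id, integer(1))
  for (n in nodes[order(ids, decreasing = TRUE)]) {
    if (!is.null(n$backward) && !is.null(n$grad)) n$backward(n)
  }
  invisible(root)
}

# ---- elementwise ops --------------------------------------------------------

ad_add <- function(a, b) {
  av <- a$value; bv <- b$value
  if (length(bv) == length(av)) {
    out <- av + bv
    ad_node(out, list(a, b), function(n) {
      ad_accum(a, n$grad); ad_accum(b, n$grad)
    })
  } else if (is.matrix(av) && length(bv) == ncol(av)) {
    # row-broadcast bias
    out <- sweep(av, 2L, bv, "+")
    ad_node(out, list(a, b), function(n) {
      ad_accum(a, n$grad); ad_accum(b, colSums(n$grad))
    })
  } else stop("ad_add: incompatible shapes")
}

ad_sub <- function(a, b) {
  ad_node(a$value - b$value, list(a, b), function(n) {
    ad_accum(a, n$grad); ad_accum(b, -n$grad)
  })
}

ad_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  stopifnot(length(av) == length(bv))
  ad_node(av * bv, list(a, b), function(n) {
    ad_accum(a, n$grad * bv); ad_accum(b, n$grad * av)
  })
}

# y = alpha * x + beta with scalar constants
ad_affine <- function(x, alpha = 1, beta = 0) {
  ad_node(alpha * x$value + beta, list(x), function(n) ad_accum(x, alpha * n$grad))
}

ad_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  ad_node(s, list(x), function(n) ad_accum(x, n$grad * s * (1 - s)))
}

ad_tanh <- function(x) {
  t <- tanh(x$value)
  ad_node(t, list(x), function(n) ad_accum(x, n$grad * (1 - t * t)))
}

ad_relu <- function(x) {
  v <- x$value
  mask <- v > 0
  ad_node(v * mask, list(x), function(n) ad_accum(x, n$grad * mask))
}

# Inverted dropout; mask drawn from the current RNG stream at build time.
ad_dropout <- function(x, p, training) {
  if (!training || p <= 0) return(x)
  keep <- array(stats::rbinom(length(x$value), 1L, 1 - p), dim = dim(x$value)) / (1 - p)
  ad_node(x$value * keep, list(x), function(n) ad_accum(x, n$grad * keep))
}

# ---- matrix / tensor ops ----------------------------------------------------

ad_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  ad_node(av %*% bv, list(a, b), function(n) {
    ad_accum(a, n$grad %*% t(bv))
    ad_accum(b, t(av) %*% n$grad)
  })
}

# Reshape without copy semantics; gradient reshaped back.
ad_reshape <- function(x, dims) {
  v <- x$value
  olddim <- if (is.null(dim(v))) length(v) else dim(v)
  dim(v) <- dims
  ad_node(v, list(x), function(n) {
    g <- n$grad
    dim(g) <- olddim
    ad_accum(x, g)
  })
}

# Batched matmul: (n,p,q) x (n,q,r) -> (n,p,r)
ad_bmm <- function(a, b) {
  av <- a$value; bv <- b$value
  da <- dim(av); db <- dim(bv)
  stopifnot(length(da) == 3L, length(db) == 3L, da[1] == db[1], da[3] == db[2])
  nB <- da[1]
  out <- array(0, dim = c(nB, da[2], db[3]))
  for (i in seq_len(nB)) {
    out[i, , ] <- matrix(av[i, , ], da[2], da[3]) %*% matrix(bv[i, , ], db[2], db[3])
  }
  ad_node(out, list(a, b), function(n) {
    g <- n$grad
    ga <- array(0, dim = da); gb <- array(0, dim = db)
    for (i in seq_len(nB)) {
      gi <- matrix(g[i, , ], da[2], db[3])
      ga[i, , ] <- gi %*% t(matrix(bv[i, , ], db[2], db[3]))
      gb[i, , ] <- t(matrix(av[i, , ], da[2], da[3])) %*% gi
    }
    ad_accum(a, ga); ad_accum(b, gb)
  })
}

# Transpose the two trailing dims of a 3-d array.
ad_perm23 <- function(x) {
  v <- aperm(x$value, c(1, 3, 2))
  ad_node(v, list(x), function(n) ad_accum(x, aperm(n$grad, c(1, 3, 2))))
}

# Shift a (B,T,C) array by `k` steps along time with zero padding (causal).
ad_shift_time <- function(x, k) {
  v <- x$value
  d <- dim(v)
  out <- array(0, dim = d)
  if (k < d[2]) out[, (k + 1):d[2], ] <- v[, 1:(d[2] - k), , drop = FALSE]
  ad_node(out, list(x), function(n) {
    g <- array(0, dim = d)
    if (k < d[2]) g[, 1:(d[2] - k), ] <- n$grad[, (k + 1):d[2], , drop = FALSE]
    ad_accum(x, g)
  })
}

# Mean over time: (B,T,C) -> (B,C)
ad_mean_time <- function(x) {
  v <- x$value
  d <- dim(v)
  out <- apply(v, c(1, 3), mean)
  dim(out) <- c(d[1], d[3])
  ad_node(out, list(x), function(n) {
    g2 <- n$grad / d[2]                          # (B,C)
    g3 <- aperm(array(g2, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
    ad_accum(x, g3)
  })
}

# Concatenate two 3-d arrays along the trailing dim.
ad_concat_last <- function(a, b) {
  av <- a$value; bv <- b$value
  da <- dim(av); db <- dim(bv)
  stopifnot(da[1] == db[1], da[2] == db[2])
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3]))
  out[, , 1:da[3]] <- av
  out[, , (da[3] + 1):(da[3] + db[3])] <- bv
  ad_node(out, list(a, b), function(n) {
    ad_accum(a, n$grad[, , 1:da[3], drop = FALSE])
    ad_accum(b, n$grad[, , (da[3] + 1):(da[3] + db[3]), drop = FALSE])
  })
}

# Stack a list of (B,C) matrices into (B,T,C).
ad_stack_time <- function(xs) {
  B <- nrow(xs[[1]]$value); C <- ncol(xs[[1]]$value); T <- length(xs)
  out <- array(0, dim = c(B, T, C))
  for (t in seq_len(T)) out[, t, ] <- xs[[t]]$value
  ad_node(out, xs, function(n) {
    for (t in seq_len(T)) {
      g <- n$grad[, t, ]
      dim(g) <- c(B, C)
      ad_accum(xs[[t]], g)
    }
  })
}

# Extract timestep t from (B,T,C) as a (B,C) matrix.
ad_slice_time <- function(x, t) {
  v <- x$value
  d <- dim(v)
  out <- v[, t, ]
  dim(out) <- c(d[1], d[3])
  ad_node(out, list(x), function(n) {
    g <- array(0, dim = d)
    g[, t, ] <- n$grad
    ad_accum(x, g)
  })
}

# Row-wise softmax of a matrix.
ad_softmax_rows <- function(x) {
  v <- x$value
  e <- exp(v - max(v))   # global-max shift is enough for stability here
  s <- e / rowSums(e)
  ad_node(s, list(x), function(n) {
    g <- n$grad
    dot <- rowSums(g * s)
    ad_accum(x, s * (g - dot))
  })
}

# Layer normalization over the columns of a matrix, per row, with gain/bias.
ad_layernorm <- function(x, gain, bias, eps = 1e-5) {
  v <- x$value
  mu <- rowMeans(v)
  xc <- v - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  out <- sweep(sweep(xhat, 2L, gain$value, "*"), 2L, bias$value, "+")
  ad_node(out, list(x, gain, bias), function(n) {
    g <- n$grad
    gx <- sweep(g, 2L, gain$value, "*")
    C <- ncol(v)
    # d/dx of (x - mu) * inv with mu, inv functions of the row
    rs_g <- rowMeans(gx)
    rs_gx <- rowMeans(gx * xhat)
    dx <- inv * (gx - rs_g - xhat * rs_gx)
    ad_accum(x, dx)
    ad_accum(gain, colSums(g * xhat))
    ad_accum(bias, colSums(g))
  })
}

# Weighted binary cross-entropy on logits (numerically stable), mean over batch.
# z: (B,1) logits node; y, w: plain numeric vectors.
ad_bce_logits <- function(z, y, w) {
  zv <- as.numeric(z$value)
  sp <- pmax(zv, 0) + log1p(exp(-abs(zv)))    # softplus(z)
  li <- w * (sp - y * zv)
  B <- length(zv)
  ad_node(mean(li), list(z), function(n) {
    p <- 1 / (1 + exp(-zv))
    g <- n$grad * w * (p - y) / B
    ad_accum(z, matrix(g, ncol = 1))
  })
}

ad_sum <- function(x) {
  ad_node(sum(x$value), list(x), function(n) {
    ad_accum(x, array(n$grad, dim = dim(x$value)))
  })
}

# ---- fused ops for the sequence backbones ----------------------------------
# These collapse hot inner structures (GRU cell, multi-head attention,
# attention pooling) into single tape nodes with hand-derived backward
# passes, which keeps the tape short on the 18-token sequences.

# Mean over time computed on the folded (B*T, C) layout.
ad_mean_time_folded <- function(x2, B, T) {
  grp <- rep(seq_len(B), T)
  out <- rowsum(x2$value, grp) / T
  ad_node(out, list(x2), function(n) {
    ad_accum(x2, n$grad[grp, , drop = FALSE] / T)
  })
}

# One GRU step. xp: (B,3w) input projection [z|r|n]; h: (B,w) previous state;
# U: (w,3w) recurrent weights; b: length-3w bias. Returns the new state.
ad_gru_step <- function(xp, h, U, b) {
  w <- ncol(h$value)
  iz <- 1:w; ir <- (w + 1):(2 * w); in_ <- (2 * w + 1):(3 * w)
  hU <- h$value %*% U$value
  bz <- b$value[iz]; br <- b$value[ir]; bn <- b$value[in_]
  z <- 1 / (1 + exp(-sweep(xp$value[, iz, drop = FALSE] + hU[, iz, drop = FALSE], 2L, bz, "+")))
  r <- 1 / (1 + exp(-sweep(xp$value[, ir, drop = FALSE] + hU[, ir, drop = FALSE], 2L, br, "+")))
  m <- sweep(hU[, in_, drop = FALSE], 2L, bn, "+")
  nn <- tanh(xp$value[, in_, drop = FALSE] + r * m)
  hnew <- (1 - z) * nn + z * h$value
  ad_node(hnew, list(xp, h, U, b), function(nd) {
    g <- nd$grad
    dn <- g * (1 - z)
    dz <- g * (h$value - nn)
    dan <- dn * (1 - nn * nn)
    dm <- dan * r
    dr <- dan * m
    dar <- dr * r * (1 - r)
    daz <- dz * z * (1 - z)
    dxp <- cbind(daz, dar, dan)
    dhU <- cbind(daz, dar, dm)
    ad_accum(xp, dxp)
    ad_accum(h, g * z + dhU %*% t(U$value))
    ad_accum(U, t(h$value) %*% dhU)
    ad_accum(b, c(colSums(daz), colSums(dar), colSums(dm)))
  })
}

# Attention pooling: out[b,] = sum_t alpha[b,t] * H[b,t,]
ad_attn_pool <- function(alpha, H) {
  av <- alpha$value; Hv <- H$value
  d <- dim(Hv); B <- d[1]; T <- d[2]; C <- d[3]
  out <- matrix(0, B, C)
  for (t in seq_len(T)) out <- out + av[, t] * matrix(Hv[, t, ], B, C)
  ad_node(out, list(alpha, H), function(n) {
    g <- n$grad
    ga <- matrix(0, B, T)
    gH <- array(0, dim = d)
    for (t in seq_len(T)) {
      Ht <- matrix(Hv[, t, ], B, C)
      ga[, t] <- rowSums(g * Ht)
      gH[, t, ] <- av[, t] * g
    }
    ad_accum(alpha, ga); ad_accum(H, gH)
  })
}

# Fused multi-head scaled dot-product self-attention.
# Q, K, V: (B,T,w) nodes; heads slice the trailing dim into n_heads blocks.
ad_mha <- function(Q, K, V, n_heads) {
  Qv <- Q$value; Kv <- K$value; Vv <- V$value
  d <- dim(Qv); B <- d[1]; T <- d[2]; w <- d[3]
  dh <- w %/% n_heads
  scale <- 1 / sqrt(dh)
  out <- array(0, dim = d)
  attn <- vector("list", B)   # per-batch list of (T, T*n_heads) softmax blocks
  for (b in seq_len(B)) {
    qb <- matrix(Qv[b, , ], T, w); kb <- matrix(Kv[b, , ], T, w); vb <- matrix(Vv[b, , ], T, w)
    Ab <- matrix(0, T, T * n_heads)
    ob <- matrix(0, T, w)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      s <- (qb[, cols, drop = FALSE] %*% t(kb[, cols, drop = FALSE])) * scale
      s <- exp(s - max(s))
      s <- s / rowSums(s)
      Ab[, ((h - 1) * T + 1):(h * T)] <- s
      ob[, cols] <- s %*% vb[, cols, drop = FALSE]
    }
    attn[[b]] <- Ab
    out[b, , ] <- ob
  }
  ad_node(out, list(Q, K, V), function(n) {
    g <- n$grad
    gQ <- array(0, dim = d); gK <- array(0, dim = d); gV <- array(0, dim = d)
    for (b in seq_len(B)) {
      qb <- matrix(Qv[b, , ], T, w); kb <- matrix(Kv[b, , ], T, w); vb <- matrix(Vv[b, , ], T, w)
      gb <- matrix(g[b, , ], T, w)
      Ab <- attn[[b]]
      for (h in seq_len(n_heads)) {
        cols <- ((h - 1) * dh + 1):(h * dh)
        s <- Ab[, ((h - 1) * T + 1):(h * T)]
        go <- gb[, cols, drop = FALSE]
        gV[b, , cols] <- t(s) %*% go
        dS <- go %*% t(vb[, cols, drop = FALSE])
        dA <- s * (dS - rowSums(dS * s))
        gQ[b, , cols] <- (dA %*% kb[, cols, drop = FALSE]) * scale
        gK[b, , cols] <- (t(dA) %*% qb[, cols, drop = FALSE]) * scale
      }
    }
    ad_accum(Q, gQ); ad_accum(K, gK); ad_accum(V, gV)
  })
}
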