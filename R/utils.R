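# Shared helpers: validation, deterministic string hashing for per-subject
# RNG substreams, and local-seed evaluation.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gaitxai <- function(fmt, ..., class = "gaitxai_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

assert_that <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stop_gaitxai(fmt, ...)
  invisible(TRUE)
}

# FNV-1a style 32-bit hash folded into [0, 2^31 - 2]; used to derive stable
# per-subject RNG substreams independent of generation order.
hash_string <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483646L)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Derive a child seed from a base seed and a label, kept below 2^31.
derive_seed <- function(base_seed, label) {
  as.integer((as.numeric(base_seed) + hash_string(as.character(label))) %% 2147483647)
}
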