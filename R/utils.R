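# Internal helpers: seeded evaluation and seed derivation.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state on
# exit so that simulation helpers never perturb global random state.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seed from a base seed and integer indices; stays within
# 32-bit integer range (R integers) and is never 0.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  v <- as.double(seed) %% 2147483647
  for (k in seq_along(idx)) {
    v <- (v * 48271 + as.double(idx[k]) * 1299721 + k * 7919) %% 2147483647
  }
  as.integer(v) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
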