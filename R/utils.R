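# Shared internal helpers: seed management and small validators.

# Evaluate `expr` under `seed` (restoring the caller's RNG state), or as-is
# when seed is NULL.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Deterministic per-stage seeds from a root seed: a counter-based split via a
# Lehmer step, kept strictly below 2^31 so the result is a valid R seed.
derive_seeds <- function(root, n) {
  root <- as.integer(root)
  m <- 2147483647
  s <- root %% m
  out <- integer(n)
  for (i in seq_len(n)) {
    s <- as.integer((48271 * (s %% 44488) - 3399 * (s %/% 44488)) %% m)
    if (s <= 0) s <- s + m - 1L
    out[i] <- s
  }
  as.list(out)
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single proportion in [0, 1]", name))
  }
  x
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number", name))
  }
  x
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0) {
    abort(sprintf("`%s` must be a single non-negative number", name))
  }
  x
}
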