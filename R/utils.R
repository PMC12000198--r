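# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (finite && !is.finite(x))) {
    stop("`", name, "` must be a single finite number.", call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    stop("`", name, "` must be a positive integer.", call. = FALSE)
  }
  invisible(as.integer(x))
}

# Evaluate `expr` under a locally seeded RNG without touching global RNG
# state when `seed` is NULL.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  withr::with_seed(as.integer(seed), expr)
}

# Documented seed-splitting rule: under the master seed, draw one sub-seed
# per stream from the integers below 2^31 - 1. Deterministic per master
# seed; sub-streams are independent Mersenne-Twister streams.
split_seed <- function(seed, n) {
  with_seed_if(seed, sample.int(.Machine$integer.max - 1L, n))
}

# log(exp(lx) - exp(ly)) for lx >= ly, without underflow.
logspace_sub <- function(lx, ly) {
  if (ly == -Inf) return(lx)
  lx + log1p(-exp(ly - lx))
}
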