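# Deterministic sub-stream derivation: one master seed reproduces every draw,
# and per-call-site keys keep parallel and serial execution identical.
# Kept strictly below 2^31 so the result is always a valid integer seed.
derive_seed <- function(seed, key) {
  s <- as.numeric(seed) %% 2147483647
  as.integer(((s * 69069 + as.numeric(key)) %% 2147483646) + 1)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# Overflow-safe log(1 + exp(u))
log1pexp <- function(u) {
  out <- u
  pos <- u > 0
  out[pos] <- u[pos] + log1p(exp(-u[pos]))
  out[!pos] <- log1p(exp(u[!pos]))
  out
}

assert_finite_matrix <- function(x, what = "features") {
  if (!all(is.finite(x))) {
    abort(sprintf("non-finite entries in %s", what), class = "lfire_data_error")
  }
  invisible(x)
}
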