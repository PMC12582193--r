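# RNG helpers. All stochastic entry points take an integer seed and evaluate
# under a locally-seeded RNG, restoring the caller's RNG state afterwards, so
# the same seed always gives the same output no matter what ran before.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and one or more small integer keys.
# Stays inside [0, 2^31) so it is always a valid R integer seed.
derive_seed <- function(seed, ...) {
  keys <- c(...)
  x <- as.double(seed) %% 2147483647
  for (k in keys) {
    x <- (x * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(x)
}
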