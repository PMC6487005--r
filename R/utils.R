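# Run code under an explicit integer seed without disturbing the
# caller's RNG state. All stochastic operations in the package route
# their randomness through this helper.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Deterministic per-repeat seed derivation from a master seed, kept
# within 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) + as.double(index)) %% .Machine$integer.max)
}
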