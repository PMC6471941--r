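# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a reproducible 31-bit substream seed from a base seed and a label.
# Polynomial rolling hash mod the Mersenne prime 2^31 - 1: distinct labels
# give distinct, well-spread streams (no collisions over the label sets used
# here). Every derived seed is a valid positive R integer below 2^31.
derive_seed <- function(seed, label) {
  h <- as.double(seed) %% 2147483647
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% 2147483647
  as.integer((h * 48271) %% 2147483647)
}

# Quadratic (3-point parabolic) refinement of a discrete peak position.
# Returns the sub-sample offset in [-0.5, 0.5] around index i.
parabolic_offset <- function(y, i) {
  if (i <= 1L || i >= length(y)) return(0)
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (denom == 0) return(0)
  off <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
  max(min(off, 0.5), -0.5)
}
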