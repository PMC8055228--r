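# Internal helpers shared across modules.

# Derive a reproducible 31-bit substream seed from a base seed, a counter and
# a stream label, so every source of randomness (SGD shuffles, factor init,
# the random control strategy, trial seeds) fans out from one session seed.
derive_seed <- function(seed, counter = 0L, stream = "") {
  h <- sum(utf8ToInt(paste0("s", stream))) %% 1000003L
  s <- (as.double(seed) * 48271 + as.double(counter) * 10007 + h) %% 2147483629
  as.integer(s + 1)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so internal seeding never perturbs user-level streams.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Clamp predictions to the legal score range. Used only when predictions are
# surfaced as recommendations; training residuals are computed on raw values.
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
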