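# Run code with a private RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards so that library calls do not perturb user simulations.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  code
}

# Deterministic sub-seed for a named substream (trees, mutations, effects,
# meiosis, ...) so that one top-level seed governs all sources of randomness.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629)
}
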