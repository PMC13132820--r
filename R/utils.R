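# RNG hygiene: run code under a given seed, restoring the caller's
# .Random.seed afterwards so package functions never disturb the global
# stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Deterministic child seed for an independent pseudo-stream, so toggling
# one stage (folds / permutations / bootstraps) does not shift another.
# Kept inside 32-bit integer range.
child_seed <- function(master, stream) {
  as.integer(((as.numeric(master) %% 2147483647) * 48271 +
                as.numeric(stream) * 104729) %% 2147483629 + 1)
}
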