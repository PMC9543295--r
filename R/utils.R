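# Run code with a temporarily fixed RNG seed, restoring the caller's RNG
# state afterwards, so generators are pure functions of their seed arguments.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Splittable per-case seed derivation: deterministic, collision-free for
# practical cohort sizes, always a valid 32-bit R integer, and extensible
# (case i's seed does not depend on the number of cases).
derive_seed <- function(master, i) {
  as.integer(((as.double(master) %% 65536) * 32749 + as.double(i) * 7919) %% 2147483647)
}
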