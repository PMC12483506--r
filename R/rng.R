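# Internal RNG plumbing: every user-facing stochastic function takes an
# explicit `seed` and runs under a local RNG state, so package calls never
# disturb the caller's .Random.seed and identical seeds give identical output.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-stream seed from a run seed and a stage label, so enabling
# or disabling one pipeline stage never changes another stage's draws.
# Plain 31-bit polynomial string hash folded with the run seed.
derive_seed <- function(seed, label) {
  h <- as.numeric(as.integer(seed)) %% 2147483647
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}
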