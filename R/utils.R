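# Run code with a private RNG stream: seed it, evaluate, restore the
# caller's RNG state so package functions never perturb user randomness.
with_preserved_rng <- function(seed, expr) {
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

# Derive a bounded sub-seed from a master seed and a stream index, so each
# simulated field draws from its own reproducible stream.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) + 999983 * as.numeric(stream)) %% 2147483629) + 1L
}

fmt_ci <- function(est, lo, hi, digits = 2) {
  f <- function(v) {
    if (is.na(v)) "NR" else formatC(v, digits = digits, format = "fg")
  }
  sprintf("%s (%s-%s)", f(est), f(lo), f(hi))
}
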