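## Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. Keeps library-level determinism
# without clobbering user RNG state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# stable, locale-independent character sort (C collation)
csort <- function(x) sort(x, method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a
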