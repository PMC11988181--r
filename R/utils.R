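# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All seeded package functions route
# through this so that user RNG state is never clobbered.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Structured progress note to stderr; results never go to stdout.
logMsg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

# sigma(UP) = +1, sigma(DOWN) = -1 for modes of action;
# sigma(log2fc >= 0) = +1, sigma(log2fc < 0) = -1 for disease genes.
moaSign <- function(moa) ifelse(moa == "DOWN", -1, 1)
fcSign <- function(log2fc) ifelse(log2fc < 0, -1, 1)
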