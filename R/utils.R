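## Internal helpers shared across modules.

## Run `expr` under a private RNG state seeded with `seed`, restoring the
## caller's state afterwards.  Keeps every stochastic operation in the
## package reproducible and side-effect free.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

## Derive k reproducible child seeds from one parent seed (kept < 2^31).
childSeeds <- function(seed, k) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, k))
}

## Round half away from zero ("half up" for the non-negative stage scale).
roundHalfUp <- function(x, digits = 0L) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

stopifnotScalarPositive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name),
      call. = FALSE)
  invisible(x)
}
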