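#' Evaluate code under a fixed RNG seed, restoring the RNG state afterwards
#'
#' All stochastic generators in the package route their randomness through
#' this helper so that a given seed yields byte-identical output regardless
#' of the surrounding RNG state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

## stable spawn of sub-seeds so that independent generators called with the
## same master seed do not share streams
spawnSeed <- function(seed, k) {
  ## numeric arithmetic stays exact well past 2^31, so no overflow
  as.integer((as.numeric(seed) * 1009 + as.numeric(k) * 9176) %%
               2147483562) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
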