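#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so seeded generators do not disturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
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
  set.seed(as.integer(seed))
  expr
}

# Spawn `n` child seeds from a master seed, all < 2^31.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
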