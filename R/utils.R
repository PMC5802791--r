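# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded generators do not perturb surrounding code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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

#' Derive a stream of child seeds from one master seed
#'
#' Deterministically expands a master seed into `n` independent 31-bit child
#' seeds, so each pipeline stage / replicate gets its own reproducible stream.
#'
#' @param seed master seed (integer).
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  # headroom below 2^31 so callers may offset child seeds by small integers
  with_seed(seed, sample.int(.Machine$integer.max - 1000L, n, replace = FALSE))
}

# logit / inverse logit on the probability scale used throughout
logit <- function(p) stats::qlogis(p)
inv_logit <- function(x) stats::plogis(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_memloop <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "memloop_error")))
}
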