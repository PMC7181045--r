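#' Evaluate code with a temporary RNG seed
#'
#' Runs \code{code} with the global random number generator seeded at
#' \code{seed}, then restores the previous RNG state, so seeded package
#' internals never disturb a user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Capture the current global RNG state (or NULL if none exists yet).
get_rng_state <- function() {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv, inherits = FALSE)
  else NULL
}

set_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
  invisible(state)
}

# log(sum(exp(x))) along rows of a matrix, guarded against underflow.
row_logsumexp <- function(lx) {
  m <- apply(lx, 1L, max)
  m + log(rowSums(exp(lx - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
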