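# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# round() in R rounds half to even; printed train/test sizes need half-up
round_half_up <- function(x) floor(x + 0.5)

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the RNG with `seed`, evaluates `code`, then restores the caller's
#' RNG state so library code never perturbs a user's random stream.
#' A `NULL` seed evaluates `code` against the current stream unchanged.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# missing marker: NA or empty string
is_blank <- function(x) {
  is.na(x) | (if (is.character(x)) trimws(x) == "" else FALSE)
}

package_env <- new.env(parent = emptyenv())
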