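#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef dbinom lm mad median nls pnorm predict pt qt
#'   rbinom rexp rnorm rpois sd setNames t.test var
#' @importFrom utils head read.csv tail write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `code` under a fixed RNG seed, then restore the caller's RNG state.
# All stochastic functions in the package funnel through this so that a seed
# argument never has side effects on the session.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
  }
  force(code)
}

stop_if_not_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}
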