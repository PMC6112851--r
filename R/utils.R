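## Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' All generators in the package route their randomness through this helper
#' so that a fixed seed yields byte-identical output while leaving the
#' caller's RNG state untouched. A `NULL` seed evaluates the code under the
#' current RNG state.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

abort_if <- function(cond, ..., call. = FALSE) {
  if (isTRUE(cond)) stop(..., call. = call.)
  invisible(NULL)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## Nearly-integer check for bin-divisibility preconditions (ms arithmetic).
divides <- function(part, whole, tol = 1e-8) {
  r <- whole / part
  abs(r - round(r)) < tol
}
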