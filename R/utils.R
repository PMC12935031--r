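#' Evaluate an expression under a local RNG seed
#'
#' All stochastic operations in the package take an explicit seed and leave
#' the caller's RNG state untouched. `NULL` seeds run on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# assertion helper: stop with the caller-facing message when cond is FALSE
stopifnot_msg <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# derive a bounded child seed (< 2^31) from a parent seed and a stream index
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647L)
}
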