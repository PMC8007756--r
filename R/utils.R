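#' Round half away from zero
#'
#' Decimal rounding with ties going up (`round_half_up(0.5) == 1`), the
#' convention used for all printed percentages in this package. Base R's
#' `round()` rounds half to even, which disagrees on exact .5 ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector, rounded.
#' @examples
#' round_half_up(c(28.45, 11.115, 1.15), c(1, 2, 1))
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# internal: stop with a classed condition so callers/tests can match on class
abort_sleepcdm <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "sleepcdm_error"), ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
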