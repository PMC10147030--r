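#' Round half away from zero
#'
#' Commercial rounding as used throughout the reporting layer: ties are
#' rounded away from zero rather than to even (the behaviour of base
#' [round()]), so `round_half_away(97.15, 1)` is 97.2 and
#' `round_half_away(55.555, 1)` is 55.6.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_away(c(97.15, -97.15, 55.555), 1)
round_half_away <- function(x, digits = 1) {
  stopifnot(is.numeric(x), digits >= 0)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x)
}

abort_nupeval <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "nupeval_error")))
}

validation_error <- function(msg) abort_nupeval(msg, "nupeval_validation_error")
type_error       <- function(msg) abort_nupeval(msg, "nupeval_type_error")
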