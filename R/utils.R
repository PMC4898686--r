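# internal helpers

#' Round half away from zero
#'
#' Commercial rounding used for all reported dollar and CO2e figures:
#' ties go away from zero (408.72 -> 409; 416,123,500.5 -> 416,123,501),
#' unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @return `x` rounded to the nearest integer, ties away from zero.
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
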