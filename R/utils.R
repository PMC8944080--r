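#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported conversion percentages
#' follow the convention of rounding halves away from zero instead.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_away(0.5)   # 1
#' round_half_away(-0.5)  # -1
#' @export
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 1 && x == floor(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
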