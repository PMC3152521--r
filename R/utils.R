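#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for all reported dollar figures.
#' Base R's `round()` rounds half to even, which would turn e.g. a
#' half-dollar amount down; reported costs follow the usual accounting
#' convention instead. Internal computation always keeps full precision.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return `x` rounded half away from zero to `digits` places.
#' @export
#' @examples
#' round_half_up(0.5)    # 1
#' round_half_up(32.71)  # 33
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# internal: scalar numeric check
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_if_not_number <- function(x, what) {
  if (!is_number(x)) stop(sprintf("`%s` must be a single finite number", what), call. = FALSE)
  invisible(x)
}
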