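#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used for
#' display values throughout the package), unlike [base::round()] which rounds
#' ties to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(40.565, 2)   # 40.57, not 40.56
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# stop() with a consistent prefix; keeps input-validation messages uniform
abort_input <- function(...) {
  stop(paste0(...), call. = FALSE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stopifnot_scalar <- function(x, name) {
  if (!is_scalar_number(x)) {
    abort_input(name, " must be a single finite number")
  }
  invisible(x)
}
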