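# internal validation and numeric helpers

abort_field <- function(field, msg) {
  abort(sprintf("invalid `%s`: %s", field, msg), class = "evocea_validation_error")
}

check_number <- function(x, field, min = -Inf, max = Inf, allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L) {
    abort_field(field, "must be a single number")
  }
  if (is.na(x)) {
    if (allow_na) return(invisible(x))
    abort_field(field, "must not be NA")
  }
  if (x < min || x > max) {
    abort_field(field, sprintf("must be in [%s, %s], got %s", min, max, x))
  }
  invisible(x)
}

check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort_field(field, "must be TRUE or FALSE")
  }
  invisible(x)
}

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for all monetary outputs, so that
#' e.g. 0.125 rounds to 0.13 at two decimals regardless of the banker's
#' rounding used by [base::round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2, i.e. centavos).
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(2.675)      # 2.68
#' round_half_up(7.667, 1)   # 7.7
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
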