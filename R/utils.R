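#' Round half away from zero
#'
#' Base `round()` rounds half to even; reported percentages and fold changes
#' in this package follow the half-away-from-zero convention instead, so that
#' 51/56 renders as 91.1% and 48/56 as 85.7%.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded to `digits` places, ties away from zero.
#' @examples
#' round_half_up(91.07143, 1)
#' round_half_up(-2.5)
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  p <- 10^digits
  # tiny epsilon guards against 0.49999... binary representations of exact halves
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

abort_validation <- function(msg) {
  rlang::abort(msg, class = "dopaflow_validation_error")
}

stop_if_not_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_validation(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort_validation(sprintf("`%s` must be > 0 (got %g).", name, x))
  }
  if (nonneg && x < 0) {
    abort_validation(sprintf("`%s` must be >= 0 (got %g).", name, x))
  }
  invisible(x)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_validation(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
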