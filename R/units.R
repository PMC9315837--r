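#' Unit conversions
#'
#' All internal computation in mchrom uses CGS units (cm, s, mg, mL == cm^3).
#' User-facing interfaces accept flowrates in mL/min and pore radii in
#' micrometres; these helpers perform the conversions explicitly.
#'
#' @param x numeric vector to convert.
#' @return Numeric vector in the target unit.
#' @examples
#' ml_min_to_cm3_s(60) # 1 cm^3/s
#' um_to_cm(1.5)       # 1.5e-4 cm
#' @name units
NULL

#' @rdname units
#' @export
ml_min_to_cm3_s <- function(x) x / 60

#' @rdname units
#' @export
cm3_s_to_ml_min <- function(x) x * 60

#' @rdname units
#' @export
um_to_cm <- function(x) x * 1e-4

#' @rdname units
#' @export
cm_to_um <- function(x) x * 1e4

# internal: stop with a field-named validation message
abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         allow_equal_lower = FALSE, allow_equal_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_field(field, "must be a single finite number")
  }
  lo_ok <- if (allow_equal_lower) x >= lower else x > lower
  hi_ok <- if (allow_equal_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    abort_field(field, sprintf(
      "must be in %s%g, %g%s (got %g)",
      if (allow_equal_lower) "[" else "(", lower, upper,
      if (allow_equal_upper) "]" else ")", x
    ))
  }
  invisible(x)
}
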