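#' Sampled concentration signals
#'
#' A `chrom_signal` is a tibble with columns `time_s` (strictly increasing)
#' and `value` (finite; mg/mL or dimensionless c/c0), carrying a `kind`
#' attribute: `"step_response"`, `"pulse_response"` or `"inlet"`.
#'
#' @param time_s Strictly increasing sample times, s.
#' @param value Concentrations, same length.
#' @param kind One of `"step_response"`, `"pulse_response"`, `"inlet"`.
#' @return A tibble of class `chrom_signal`.
#' @examples
#' chrom_signal(0:10, pmin(0:10 / 5, 1), "step_response")
#' @export
chrom_signal <- function(time_s, value,
                         kind = c("step_response", "pulse_response", "inlet")) {
  kind <- match.arg(kind)
  if (length(time_s) != length(value)) {
    abort_field("value", "must have the same length as `time_s`")
  }
  if (length(time_s) < 2L) abort_field("time_s", "needs at least two samples")
  if (any(!is.finite(time_s)) || any(diff(time_s) <= 0)) {
    abort_field("time_s", "must be finite and strictly increasing")
  }
  if (any(!is.finite(value))) abort_field("value", "must be finite")
  if (kind == "pulse_response" && any(value < 0)) {
    abort_field("value", "pulse responses must be non-negative")
  }
  out <- tibble::tibble(time_s = as.numeric(time_s), value = as.numeric(value))
  class(out) <- c("chrom_signal", class(out))
  attr(out, "kind") <- kind
  out
}

#' @rdname chrom_signal
#' @param x Object to query.
#' @export
signal_kind <- function(x) attr(x, "kind")

#' Read and write signal CSV files
#'
#' Signals are exchanged as CSV with header `time_s,concentration` (or
#' `time_s,c_over_c0`).  Writers emit 12 significant digits.
#'
#' @param path File path.
#' @param kind Signal kind for the object returned by `read_signal_csv()`.
#' @return `read_signal_csv()`: a [chrom_signal()].
#' @export
read_signal_csv <- function(path, kind = "step_response") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df) || ncol(df) < 2L) {
    abort_field("path", "CSV must have columns `time_s` and a concentration")
  }
  vcol <- setdiff(names(df), "time_s")[1]
  chrom_signal(df$time_s, df[[vcol]], kind)
}

#' @rdname read_signal_csv
#' @param signal A [chrom_signal()].
#' @param value_name Column name for the concentration values
#'   (`"concentration"` or `"c_over_c0"`).
#' @export
write_signal_csv <- function(signal, path, value_name = "c_over_c0") {
  stopifnot(inherits(signal, "chrom_signal"))
  df <- data.frame(
    time_s = signif(signal$time_s, 12),
    v = signif(signal$value, 12)
  )
  names(df)[2] <- value_name
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# internal: linear interpolation of a signal, zero outside to the left,
# last value held to the right
signal_interp <- function(signal, t) {
  stats::approx(signal$time_s, signal$value, xout = t,
                yleft = 0, rule = 2)$y
}

#' Plot a signal
#'
#' @param object A [chrom_signal()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chrom_signal <- function(object, ...) {
  ylab <- switch(signal_kind(object),
    pulse_response = "dc/dt (1/s)",
    "c / c0"
  )
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = ylab)
}
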