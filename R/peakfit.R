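#' Fit a modified sigmoid to a breakthrough curve
#'
#' The discrete pore-bundle breakthrough is a staircase; it is regularized
#' by least-squares fitting of a shifted logistic that is exactly zero up
#' to the lag time:
#' \deqn{c(t) = a / (1 + e^{-b[(t - t_{lag}) - c]}) - a / (1 + e^{b c}),
#'       \quad t > t_{lag}}
#' and `c(t) = 0` for `t <= t_lag`.  The subtraction term enforces
#' continuity at `t = t_lag`; `a`, `b`, `c` are the three adjustable
#' parameters while `t_lag` is supplied (computed from the bundle, see
#' [t_lag()]).
#'
#' Fitting uses bounded Levenberg-Marquardt least squares over all samples
#' with `t > t_lag`, initialized from the curve itself (`a`: final value,
#' `c`: half-rise time minus `t_lag`, `b`: `4 max slope / a`), with up to
#' 5 jittered restarts (deterministic, internal seed) on failure.
#'
#' @param curve A step-response [chrom_signal()].
#' @param t_lag Lag time, s; must not exceed the first strictly positive
#'   sample time.
#' @param max_restarts Jittered restarts on non-convergence.
#' @return An object of class `sigmoid_fit` with elements `a`, `b`, `c`,
#'   `t_lag`, `ssr`, `n_points`, `plateau` (fitted value as t -> Inf) and
#'   `window` (fit time range).
#' @examples
#' col <- membrane_column(275e-4, diameter_cm = 2.2, porosity = 0.8)
#' pb <- pore_bundle(discretize_psd(1.5, 0.10), col, 1)
#' fit <- fit_sigmoid(breakthrough(pb), t_lag(pb))
#' glance(fit)
#' @export
fit_sigmoid <- function(curve, t_lag, max_restarts = 5L) {
  stopifnot(inherits(curve, "chrom_signal"))
  check_number(t_lag, "t_lag", lower = 0, allow_equal_lower = TRUE)
  first_pos <- curve$time_s[which(curve$value > 0)[1L]]
  if (!is.na(first_pos) && t_lag > first_pos) {
    abort_field("t_lag", "exceeds the first strictly positive sample time")
  }
  sel <- curve$time_s > t_lag
  td <- curve$time_s[sel]
  yd <- curve$value[sel]
  if (length(td) < 5L) abort_field("curve", "too few samples beyond t_lag")
  a0 <- yd[length(yd)]
  if (!(a0 > 0) || max(yd) - min(yd) < 1e-12) {
    abort_field("curve", "degenerate flat curve; nothing to fit")
  }
  c0 <- td[which(yd >= a0 / 2)[1L]] - t_lag
  b0 <- 4 * max(diff(yd) / diff(td)) / a0
  if (!is.finite(c0) || c0 <= 0) c0 <- (max(td) - t_lag) / 2
  if (!is.finite(b0) || b0 <= 0) b0 <- 1 / c0

  model <- function(p, t) {
    u <- p[2] * ((t - t_lag) - p[3])
    p[1] / (1 + exp(-u)) - p[1] / (1 + exp(p[2] * p[3]))
  }
  do_fit <- function(start) {
    minpack.lm::nlsLM(
      yd ~ a / (1 + exp(-b * ((td - t_lag) - cc))) - a / (1 + exp(b * cc)),
      start = list(a = start[1], b = start[2], cc = start[3]),
      lower = c(1e-12, 1e-12, 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 400)
    )
  }

  start <- c(a0, b0, c0)
  fit <- NULL
  errors <- character(0)
  # deterministic jitter; RNG state restored afterwards
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(1234L)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  for (k in 0:max_restarts) {
    st <- if (k == 0) start else start * exp(stats::rnorm(3, sd = 0.3))
    fit <- tryCatch(do_fit(st), error = function(e) {
      errors <<- c(errors, conditionMessage(e))
      NULL
    })
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("sigmoid fit did not converge after ", max_restarts,
         " restarts; last errors: ", paste(utils::tail(errors, 2), collapse = "; "),
         call. = FALSE)
  }
  p <- stats::coef(fit)
  plateau <- p[["a"]] - p[["a"]] / (1 + exp(p[["b"]] * p[["cc"]]))
  final <- yd[length(yd)]
  if (abs(plateau - final) > 0.05 * max(final, .Machine$double.eps)) {
    warning(sprintf(
      "fitted plateau %.4g deviates more than 5%% from the final value %.4g",
      plateau, final
    ), call. = FALSE)
  }
  structure(
    list(a = p[["a"]], b = p[["b"]], c = p[["cc"]], t_lag = t_lag,
         ssr = sum(stats::residuals(fit)^2), n_points = length(td),
         plateau = plateau, window = range(td)),
    class = "sigmoid_fit"
  )
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_fit> a = %.4g, b = %.4g 1/s, c = %.4g s, t_lag = %.4g s (ssr %.3g, n %d)\n",
    x$a, x$b, x$c, x$t_lag, x$ssr, x$n_points
  ))
  invisible(x)
}

#' Evaluate a fitted sigmoid
#'
#' @param fit A [fit_sigmoid()] result.
#' @param time_s Times at which to evaluate, s.
#' @return Fitted breakthrough values (0 for `t <= t_lag`).
#' @export
predict_sigmoid <- function(fit, time_s) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  u <- fit$b * ((time_s - fit$t_lag) - fit$c)
  val <- fit$a / (1 + exp(-u)) - fit$a / (1 + exp(fit$b * fit$c))
  ifelse(time_s <= fit$t_lag, 0, val)
}

#' Pulse-response peak from a sigmoid fit
#'
#' The response to an inlet pulse is the time derivative of the step
#' response.  For the fitted sigmoid this derivative is analytic:
#' \deqn{dc/dt = a b e^{-b[(t - t_{lag}) - c]} /
#'       (1 + e^{-b[(t - t_{lag}) - c]})^2, \quad t > t_{lag}}
#' with maximum `a b / 4` at `t = t_lag + c`.
#'
#' @param fit A [fit_sigmoid()] result.
#' @param time_grid Output times, s.
#' @return A pulse-response [chrom_signal()].
#' @export
derivative_peak <- function(fit, time_grid) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  u <- fit$b * ((time_grid - fit$t_lag) - fit$c)
  e <- exp(-u)
  val <- fit$a * fit$b * e / (1 + e)^2
  val[time_grid <= fit$t_lag] <- 0
  chrom_signal(time_grid, val, "pulse_response")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a sigmoid fit
#'
#' @param x A `sigmoid_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter (`a`, `b`, `c`, `t_lag`), with
#'   `fitted` indicating the adjustable ones; `glance()`: a one-row fit
#'   summary.
#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b", "c", "t_lag"),
    estimate = c(x$a, x$b, x$c, x$t_lag),
    unit = c("c/c0", "1/s", "s", "s"),
    fitted = c(TRUE, TRUE, TRUE, FALSE)
  )
}

#' @rdname tidy.sigmoid_fit
#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble::tibble(
    ssr = x$ssr, n_points = x$n_points, plateau = x$plateau,
    peak_height = x$a * x$b / 4, peak_time = x$t_lag + x$c
  )
}
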