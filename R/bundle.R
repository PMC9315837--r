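#' Parallel-pore bundle model
#'
#' Combines a pore-size distribution, a column and a flowrate into the
#' polydisperse parallel-pore description of the membrane: every pore of
#' radius `r` carries Hagen-Poiseuille flow proportional to `r^4`, so the
#' fraction of the total flow through bin k is
#' `w_k = r_k^4 weight_k / M4`, the mean velocity in a pore is
#' `v_m(r) = <v> (M2 / M4) r^2` and the residence time is
#' `tau(r) = L / v_m(r)` (`M2`, `M4`: discrete raw moments of the PSD).
#'
#' @param psd A [discretize_psd()] result.
#' @param column A [membrane_column()].
#' @param flowrate_ml_min Flowrate in mL/min.
#' @return An object of class `pore_bundle`: a tibble with columns
#'   `r_cm`, `weight` (number fraction), `flow_fraction`, `v_m` (cm/s),
#'   `tau` (s), plus attributes `column`, `flowrate_ml_min`, `v` (the
#'   interstitial velocity), `n_pores`, `M2`, `M4`.
#' @examples
#' col <- membrane_column(275e-4, diameter_cm = 2.2, porosity = 0.8)
#' pb <- pore_bundle(discretize_psd(1.5, 0.10), col, 1)
#' t_lag(pb) # ~2.94 s
#' @export
pore_bundle <- function(psd, column, flowrate_ml_min) {
  stopifnot(inherits(psd, "pore_size_distribution"),
            inherits(column, "membrane_column"))
  v <- interstitial_velocity(column, flowrate_ml_min)
  m2 <- psd_moment(psd, 2)
  m4 <- psd_moment(psd, 4)
  flow_fraction <- psd$r_cm^4 * psd$weight / m4
  v_m <- v * (m2 / m4) * psd$r_cm^2
  tau <- column$L / v_m

  out <- tibble::tibble(
    r_cm = psd$r_cm, weight = psd$weight,
    flow_fraction = flow_fraction, v_m = v_m, tau = tau
  )
  class(out) <- c("pore_bundle", class(out))
  attr(out, "column") <- column
  attr(out, "flowrate_ml_min") <- flowrate_ml_min
  attr(out, "v") <- v
  attr(out, "n_pores") <- pore_count(psd, column)
  attr(out, "M2") <- m2
  attr(out, "M4") <- m4
  out
}

#' @rdname pore_bundle
#' @param bundle A `pore_bundle`.
#' @return `flow_fractions()`: the per-bin flow weights (sum to 1).
#' @export
flow_fractions <- function(bundle) {
  stopifnot(inherits(bundle, "pore_bundle"))
  bundle$flow_fraction
}

#' @rdname pore_bundle
#' @param r_cm Pore radius (cm) at which to evaluate the mean pore velocity.
#' @return `pore_velocity()`: `v_m(r)` in cm/s.
#' @export
pore_velocity <- function(bundle, r_cm) {
  stopifnot(inherits(bundle, "pore_bundle"))
  attr(bundle, "v") * (attr(bundle, "M2") / attr(bundle, "M4")) * r_cm^2
}

#' Lag time of the bundle
#'
#' Time before any solute exits the membrane: the residence time of the
#' fastest (largest) pore retained in the effective support.
#'
#' @param bundle A [pore_bundle()].
#' @return Lag time, s.
#' @export
t_lag <- function(bundle) {
  stopifnot(inherits(bundle, "pore_bundle"))
  min(bundle$tau)
}

#' Breakthrough curve of the pore bundle
#'
#' Superposes the delayed inlet signal over all pores, weighting each by
#' its share of the flow: `c_out(t) = sum_k w_k c_in(t - tau_k)`.
#' For the default unit step inlet this is the flow-weighted fraction of
#' pores with residence time below `t`.
#'
#' The default time grid runs to the time at which `c_out/c0` first
#' exceeds 0.999, extended by 20%, in `n_time` uniform steps.
#'
#' @param bundle A [pore_bundle()].
#' @param time_grid Optional vector of output times, s.
#' @param inlet Optional [chrom_signal()] inlet; default is a unit step at
#'   t = 0.
#' @param n_time Number of grid intervals for the default grid.
#' @param extend Factor extending the default grid past the 0.999 crossing.
#' @return A step-response [chrom_signal()].  With the default step inlet
#'   the values are exact partial sums of flow fractions (no smoothing).
#' @export
breakthrough <- function(bundle, time_grid = NULL, inlet = NULL,
                         n_time = 4000, extend = 1.2) {
  stopifnot(inherits(bundle, "pore_bundle"))
  ord <- order(bundle$tau)
  tau_s <- bundle$tau[ord]
  cum_w <- cumsum(bundle$flow_fraction[ord])

  t999 <- tau_s[which(cum_w >= 0.999)[1L]]
  if (is.null(time_grid)) {
    time_grid <- seq(0, t999 * extend, length.out = n_time + 1L)
  }
  if (max(time_grid) < t999) {
    warning("time grid ends before 99.9% of the flow has broken through ",
            "(truncated tail)", call. = FALSE)
  }

  if (is.null(inlet)) {
    val <- stats::approx(tau_s, cum_w, xout = time_grid,
                         method = "constant", yleft = 0, rule = 2)$y
  } else {
    stopifnot(inherits(inlet, "chrom_signal"))
    val <- vapply(time_grid, function(t) {
      sum(bundle$flow_fraction * signal_interp(inlet, t - bundle$tau))
    }, numeric(1))
  }
  chrom_signal(time_grid, val, "step_response")
}
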