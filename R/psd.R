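#' Discretized truncated Gaussian pore-size distribution
#'
#' Pore radii are modelled as Gaussian,
#' `f(r) = exp(-((r - mu)/sigma)^2 / 2) / (sqrt(2 pi) sigma)`,
#' truncated to an effective support and renormalized.  The support is the
#' intersection of the nominal bounds `[r_min, r_max]` with the region where
#' the density exceeds a relative threshold `theta` of its mode, i.e.
#' `mu +/- m sigma` with `m = sqrt(2 log(1/theta))`.  The support is divided
#' into `n_bins` uniform bins; midpoint densities define weights
#' `w_k = f(r_k) dr / sum_j f(r_j) dr` which sum to one.
#'
#' @param mu_um Mean pore radius, micrometres.
#' @param sigma_um Standard deviation, micrometres (> 0).
#' @param rmin_um,rmax_um Nominal minimum and maximum pore radius, um.
#' @param theta Relative-density support threshold (0 < theta < 1).
#' @param n_bins Number of uniform radius bins.
#' @return A tibble of class `pore_size_distribution` with columns
#'   `r_cm` (bin midpoints), `density` (truncated Gaussian density) and
#'   `weight` (normalized number fractions), plus attributes
#'   `mu`, `sigma`, `dr`, `support` (all in cm) and `n_bins`.
#' @examples
#' psd <- discretize_psd(1.5, 0.10)
#' sum(psd$weight) # 1
#' @export
discretize_psd <- function(mu_um, sigma_um, rmin_um = 0.50, rmax_um = 6.50,
                           theta = 1e-5, n_bins = 600) {
  check_number(mu_um, "mu_um", lower = 0)
  check_number(sigma_um, "sigma_um", lower = 0)
  check_number(rmin_um, "rmin_um", lower = 0, allow_equal_lower = TRUE)
  check_number(rmax_um, "rmax_um", lower = rmin_um)
  check_number(theta, "theta", lower = 0, upper = 1)
  if (!(rmin_um < mu_um && mu_um < rmax_um)) {
    abort_field("mu_um", "mean must lie strictly inside [rmin_um, rmax_um]")
  }
  if (!is.numeric(n_bins) || n_bins < 1) abort_field("n_bins", "must be >= 1")
  n_bins <- as.integer(n_bins)

  mu <- um_to_cm(mu_um); sigma <- um_to_cm(sigma_um)
  m <- sqrt(2 * log(1 / theta))
  lo <- max(um_to_cm(rmin_um), mu - m * sigma)
  hi <- min(um_to_cm(rmax_um), mu + m * sigma)
  if (!(hi > lo)) abort_field("theta", "effective support is empty")

  edges <- seq(lo, hi, length.out = n_bins + 1L)
  r <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  dr <- (hi - lo) / n_bins
  density <- stats::dnorm(r, mean = mu, sd = sigma)
  weight <- density * dr
  weight <- weight / sum(weight)

  out <- tibble::tibble(r_cm = r, density = density, weight = weight)
  class(out) <- c("pore_size_distribution", class(out))
  attr(out, "mu") <- mu
  attr(out, "sigma") <- sigma
  attr(out, "dr") <- dr
  attr(out, "support") <- c(lo, hi)
  attr(out, "n_bins") <- n_bins
  out
}

# internal: discrete raw moments of the PSD, sum r^k weight
psd_moment <- function(psd, k) sum(psd$r_cm^k * psd$weight)

#' Total pore count of the bed
#'
#' The number of parallel cylindrical pores needed so that their total
#' cross-section fills the void area:
#' `n_p = eps A / (pi M2)` with `M2` the discrete second raw moment of
#' the pore-radius distribution.
#'
#' @param psd A [discretize_psd()] result.
#' @param column A [membrane_column()].
#' @return Number of pores (a large positive number, not rounded).
#' @export
pore_count <- function(psd, column) {
  stopifnot(inherits(psd, "pore_size_distribution"),
            inherits(column, "membrane_column"))
  column$porosity * column$A / (pi * psd_moment(psd, 2))
}

#' Hagen-Poiseuille flow through one pore
#'
#' Laminar flow through a cylinder of radius `r_cm` and length equal to the
#' membrane thickness, under a pressure difference `delta_p` with fluid
#' viscosity `eta`: `F(r) = pi delta_p r^4 / (8 eta L)`.  Units must form a
#' consistent system (CGS: dyn/cm^2 and poise give cm^3/s).
#'
#' Note the pressure drop and viscosity cancel in all flow-fraction and
#' velocity formulas; they are only needed for this absolute flow.
#'
#' @param r_cm Pore radius, cm.
#' @param column A [membrane_column()] (supplies the length).
#' @param delta_p Pressure difference (> 0).
#' @param eta Dynamic viscosity (> 0).
#' @return Volumetric flow per pore.
#' @export
pore_flowrate <- function(r_cm, column, delta_p, eta) {
  stopifnot(inherits(column, "membrane_column"))
  check_number(delta_p, "delta_p", lower = 0)
  check_number(eta, "eta", lower = 0)
  delta_p * pi * r_cm^4 / (8 * eta * column$L)
}

#' Plot a discretized pore-size distribution
#'
#' @param object A [discretize_psd()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pore_size_distribution <- function(object, ...) {
  df <- tibble::tibble(r_um = cm_to_um(object$r_cm), density = object$density)
  ggplot2::ggplot(df, ggplot2::aes(.data$r_um, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pore radius (um)", y = "density (1/cm)")
}
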