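# Independent closed-form and fixture helpers shared across tests.
# These deliberately re-derive quantities without calling the package
# functions they are used to check.

# Outlet response of 1-D advection-dispersion on a semi-infinite domain to
# a concentration step at the inlet (classical erfc solution).  The image
# term exp(vL/D) * erfc(...) is evaluated in log space because erfc
# underflows long before the product becomes negligible.
step_response_closed_form <- function(t, L, v, D) {
  t <- pmax(t, .Machine$double.eps)
  x1 <- (L - v * t) / (2 * sqrt(D * t))
  x2 <- (L + v * t) / (2 * sqrt(D * t))
  lg <- v * L / D + log(2) + pnorm(-x2 * sqrt(2), log.p = TRUE)
  0.5 * (2 * pnorm(-x1 * sqrt(2)) + exp(pmin(lg, 700)))
}

# Membrane disc used throughout: 2.2 cm diameter, 275 um thick, 80% void
disc_column <- function() {
  membrane_column(thickness_cm = 275e-4, diameter_cm = 2.2, porosity = 0.8)
}

# Stacked experimental column: 5 layers, 0.1 cm, 3.8 cm^2, 54.5% void
stack_column <- function() {
  membrane_column(thickness_cm = 0.1, area_cm2 = 3.8, porosity = 0.545,
                  n_layers = 5L)
}

bi_langmuir_iso <- function() {
  isotherm("bi_langmuir", q_m_irr = 4.75, k_d_irr = 0,
           q_m_rev = 7.00, k_d_rev = 1.15)
}

# Configuration equivalent to inst/extdata/sartobind_psd.yaml, built in code
psd_config <- function(sigma_um = 0.10, flowrate_ml_min = 1) {
  structure(
    list(
      column = disc_column(),
      conditions = operating_conditions(flowrate_ml_min),
      isotherm = NULL,
      psd = list(mu_um = 1.50, sigma_um = sigma_um, rmin_um = 0.50,
                 rmax_um = 6.50, theta = 1e-5, n_bins = 600),
      extra_column = NULL, dispersion = NULL,
      numerics = list(), moments = list(epsilon_in_moments = FALSE)
    ),
    class = "mchrom_config"
  )
}

# Raw moments of an untruncated Gaussian (mu, sigma): E r^2 and E r^4
gauss_m2 <- function(mu, sigma) mu^2 + sigma^2
gauss_m4 <- function(mu, sigma) mu^4 + 6 * mu^2 * sigma^2 + 3 * sigma^4
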