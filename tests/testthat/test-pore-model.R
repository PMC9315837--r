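test_that("PSD discretization matches the Gaussian and its truncation rule", {
  psd <- discretize_psd(1.5, 0.10, theta = 1e-5)
  # support edge: mu + sqrt(2 ln 1e5) sigma = mu + 4.7985 sigma
  m <- sqrt(2 * log(1e5))
  expect_equal(attr(psd, "support")[2], um_to_cm(1.5 + m * 0.10),
               tolerance = 1e-12)
  expect_equal(attr(psd, "support")[1], um_to_cm(1.5 - m * 0.10),
               tolerance = 1e-12)
  expect_equal(sum(psd$weight), 1, tolerance = 1e-12)
  # density at the mode (nearest bin midpoint)
  imid <- which.min(abs(psd$r_cm - um_to_cm(1.5)))
  expect_equal(psd$density[imid], 1 / (sqrt(2 * pi) * um_to_cm(0.10)),
               tolerance = 2e-4)

  # broad distribution is clipped by the nominal minimum radius
  broad <- discretize_psd(1.5, 0.35, rmin_um = 0.5, rmax_um = 6.5)
  expect_equal(attr(broad, "support")[1], um_to_cm(0.5), tolerance = 1e-12)
  expect_equal(attr(broad, "support")[2], um_to_cm(1.5 + m * 0.35),
               tolerance = 1e-12)

  # monodisperse limit: the whole retained support collapses onto mu
  mono <- discretize_psd(1.5, 1e-6, n_bins = 51)
  expect_equal(sum(mono$weight), 1, tolerance = 1e-12)
  expect_true(all(abs(mono$r_cm - um_to_cm(1.5)) / um_to_cm(1.5) < 1e-5))

  expect_error(discretize_psd(1.5, 0.1, rmin_um = 2, rmax_um = 6.5), "mu_um")
})

test_that("pore count fills the void area", {
  # near-monodisperse pores of 1 cm radius in a bed with eps*A = pi:
  # exactly one pore
  col <- membrane_column(0.1, area_cm2 = pi / 0.8, porosity = 0.8)
  mono <- discretize_psd(1e4, 1e-3, rmin_um = 0.9e4, rmax_um = 1.1e4)
  expect_equal(pore_count(mono, col), 1, tolerance = 1e-9)

  # doubling the area doubles the count
  col2 <- membrane_column(0.1, area_cm2 = 2 * pi / 0.8, porosity = 0.8)
  expect_equal(pore_count(mono, col2), 2 * pore_count(mono, col),
               tolerance = 1e-12)

  # second moment of the sigma = 0.10 um distribution: mu^2 + sigma^2
  psd <- discretize_psd(1.5, 0.10)
  m2 <- sum(psd$r_cm^2 * psd$weight)
  expect_equal(m2, gauss_m2(um_to_cm(1.5), um_to_cm(0.10)), tolerance = 1e-4)
  disc <- disc_column()
  expect_equal(pore_count(psd, disc), 0.8 * disc$A / (pi * m2),
               tolerance = 1e-12)
})

test_that("per-pore flow follows Hagen-Poiseuille", {
  col <- membrane_column(0.1, area_cm2 = 1, porosity = 0.5)
  f1 <- pore_flowrate(1e-4, col, delta_p = 1e4, eta = 0.01)
  expect_equal(pore_flowrate(2e-4, col, 1e4, 0.01) / f1, 16, tolerance = 1e-12)
  col2 <- membrane_column(0.2, area_cm2 = 1, porosity = 0.5)
  expect_equal(pore_flowrate(1e-4, col2, 1e4, 0.01) / f1, 0.5,
               tolerance = 1e-12)
  # identity construction: delta_p = 8 eta L / (pi r^4) gives unit flow
  r <- 3e-4
  expect_equal(pore_flowrate(r, col, 8 * 0.01 * col$L / (pi * r^4), 0.01), 1,
               tolerance = 1e-12)
})

test_that("flow fractions follow the r^4 law and normalize", {
  # two equal-number bins at radii r and 2r: flow split 1/17 vs 16/17.
  # A huge sigma makes the density flat; support [a, 5a] puts the two
  # midpoints at 2a and 4a.
  psd2 <- discretize_psd(3e-1, 1e6, rmin_um = 1e-1, rmax_um = 5e-1,
                         theta = 0.9999, n_bins = 2)
  col <- disc_column()
  pb <- pore_bundle(psd2, col, 1)
  expect_equal(pb$flow_fraction, c(1 / 17, 16 / 17), tolerance = 1e-9)

  # normalization across the broad nominal grid
  pb35 <- pore_bundle(discretize_psd(1.5, 0.35), col, 1)
  expect_equal(sum(flow_fractions(pb35)), 1, tolerance = 1e-12)

  # monodisperse: with all radii equal, flow fractions equal number
  # fractions
  mono <- pore_bundle(discretize_psd(1.5, 1e-6, n_bins = 51), col, 1)
  expect_lt(max(abs(flow_fractions(mono) - mono$weight)), 1e-4)
})

test_that("pore velocities scale as r^2 with the M2/M4 prefactor", {
  col <- disc_column()
  v <- interstitial_velocity(col, 1)

  # monodisperse: v_m(mu) = <v>
  mono <- pore_bundle(discretize_psd(1.5, 1e-6, n_bins = 51), col, 1)
  expect_equal(pore_velocity(mono, um_to_cm(1.5)), v, tolerance = 1e-8)

  # sigma = 0.10: M2/M4 from untruncated Gaussian raw moments
  pb <- pore_bundle(discretize_psd(1.5, 0.10), col, 1)
  ratio <- gauss_m2(um_to_cm(1.5), um_to_cm(0.10)) /
    gauss_m4(um_to_cm(1.5), um_to_cm(0.10))
  expect_equal(attr(pb, "M2") / attr(pb, "M4"), ratio, tolerance = 1e-3)

  expect_true(all(diff(pb$v_m) > 0))
  expect_true(all(diff(pb$tau) < 0))

  # algebraic identity: flow-weighted mean residence time = L / <v>
  expect_equal(sum(pb$flow_fraction * pb$tau), col$L / v, tolerance = 1e-10)
})

test_that("bundle flow adds up to the imposed flowrate", {
  col <- disc_column()
  psd <- discretize_psd(1.5, 0.18)
  pb <- pore_bundle(psd, col, 1)
  np <- attr(pb, "n_pores")
  eta <- 0.01
  # back out the pressure drop from the total-flow relation, then check
  # that summing per-pore Hagen-Poiseuille flows recovers F
  m4 <- attr(pb, "M4")
  f_total <- ml_min_to_cm3_s(1)
  delta_p <- 8 * eta * col$L * f_total / (pi * np * m4)
  per_pore <- pore_flowrate(pb$r_cm, col, delta_p, eta)
  expect_equal(sum(np * pb$weight * per_pore), f_total, tolerance = 1e-10)
})

test_that("breakthrough superposes delayed steps", {
  col <- disc_column()
  v <- interstitial_velocity(col, 1)

  # monodisperse: a delayed step at L/<v>
  mono <- pore_bundle(discretize_psd(1.5, 1e-6, n_bins = 51), col, 1)
  bt <- breakthrough(mono, time_grid = seq(0, 4 * col$L / v, length.out = 8001))
  jump <- bt$time_s[which(bt$value > 0.5)[1]]
  expect_equal(jump, col$L / v, tolerance = 5e-3)

  # polydisperse: monotone, bounded, zero before t_lag
  pb <- pore_bundle(discretize_psd(1.5, 0.26), col, 1)
  bt <- breakthrough(pb)
  expect_true(all(diff(bt$value) >= 0))
  expect_true(all(bt$value >= 0 & bt$value <= 1))
  expect_true(all(bt$value[bt$time_s < t_lag(pb)] == 0))

  # first moment of the breakthrough derivative = L/<v>
  dv <- diff(bt$value)
  tm <- (bt$time_s[-1] + bt$time_s[-nrow(bt)]) / 2
  mu1 <- sum(dv * tm) / sum(dv)
  expect_equal(mu1, col$L / v, tolerance = 5e-3)

  # a short grid warns about the truncated tail
  expect_warning(breakthrough(pb, time_grid = seq(0, t_lag(pb) * 1.5,
                                                  length.out = 50)),
                 "truncated")
})

test_that("pure bundle model is self-similar in t * <v>", {
  col <- disc_column()
  psd <- discretize_psd(1.5, 0.18)
  pb1 <- pore_bundle(psd, col, 1)
  pb5 <- pore_bundle(psd, col, 5)
  tg <- seq(0, 12, length.out = 3001)
  bt1 <- breakthrough(pb1, time_grid = tg)
  bt5 <- breakthrough(pb5, time_grid = tg / 5)
  expect_equal(bt5$value, bt1$value, tolerance = 1e-12)
})

test_that("discrete peak variance matches the closed-form flow-weighted
           variance of residence times", {
  cfg <- psd_config(sigma_um = 0.18)
  cfg$psd$n_bins <- 500
  raw <- psd_to_dispersion(cfg, smooth = "none")
  oracle <- bundle_dispersion_oracle(raw$bundle)
  expect_equal(raw$D_L, oracle, tolerance = 5e-3)
})
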