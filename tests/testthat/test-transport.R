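test_that("non-binding solver reproduces the closed-form step response", {
  col <- disc_column()
  cond <- operating_conditions(1, c0_mg_ml = 1)
  v <- interstitial_velocity(col, 1)
  pe <- 200
  d_l <- v * col$L / pe
  tg <- seq(0, 3 * col$L / v, length.out = 300)
  sol <- solve_transport(col, cond, iso = NULL, d_l = d_l, time_grid = tg,
                         grid = pde_grid(n_cells = 400))
  exact <- step_response_closed_form(tg, col$L, v, d_l)
  expect_lt(max(abs(sol$value - exact)), 1e-3)
})

test_that("low-dispersion limit tends to a plug-flow step at L/<v>", {
  col <- disc_column()
  cond <- operating_conditions(1)
  v <- interstitial_velocity(col, 1)
  d_l <- v * col$L / 2000
  tg <- seq(0, 2.5 * col$L / v, length.out = 300)
  sol <- solve_transport(col, cond, NULL, d_l, time_grid = tg)
  t50 <- approx(sol$value, tg, xout = 0.5, ties = "ordered")$y
  expect_equal(t50, col$L / v, tolerance = 5e-3)
  expect_true(all(diff(sol$value) > -1e-6))
  expect_true(all(sol$value <= 1 + 1e-6))
})

test_that("adsorbing front sits at the stoichiometric position and
           conserves mass", {
  col <- stack_column()
  cond <- operating_conditions(1, c0_mg_ml = 0.48)
  iso <- bi_langmuir_iso()
  v <- interstitial_velocity(col, 1)
  d_l <- 0.104 * v
  q0 <- equilibrium_loading(iso, 0.48)
  t_st <- col$L / v * (1 + (1 - col$porosity) / col$porosity * q0 / 0.48)

  tg <- seq(0, 3 * t_st, length.out = 801)
  sol <- solve_transport(col, cond, iso, d_l, time_grid = tg,
                         grid = pde_grid(n_cells = 150))
  expect_gt(sol$value[length(tg)] / 0.48, 0.999)

  mb <- transport_mass_balance(sol)
  expect_lt(abs(mb$relative_residual), 5e-3)

  # centre of mass of the front equals the integral mass balance
  cc <- sol$value / 0.48
  com <- sum(diff(tg) * (1 - (cc[-1] + cc[-length(cc)]) / 2))
  expect_equal(com, t_st, tolerance = 0.01)
})

test_that("halving the cell size leaves the half-breakthrough time
           unchanged to 0.5%", {
  col <- stack_column()
  cond <- operating_conditions(1, c0_mg_ml = 0.48)
  iso <- bi_langmuir_iso()
  v <- interstitial_velocity(col, 1)
  tg <- seq(0, 500, length.out = 501)
  t50 <- vapply(c(100, 200), function(n) {
    sol <- solve_transport(col, cond, iso, 0.104 * v, time_grid = tg,
                           grid = pde_grid(n_cells = n))
    approx(sol$value / 0.48, tg, xout = 0.5, ties = "ordered")$y
  }, numeric(1))
  expect_lt(abs(diff(t50)) / t50[1], 5e-3)
})

test_that("an all-zero isotherm reduces to the non-binding equation", {
  col <- disc_column()
  cond <- operating_conditions(1)
  v <- interstitial_velocity(col, 1)
  d_l <- v * col$L / 100
  tg <- seq(0, 3 * col$L / v, length.out = 200)
  none <- isotherm("langmuir", q_m = 0, k_d = 1)
  a <- solve_transport(col, cond, none, d_l, time_grid = tg,
                       inlet_bc = "dirichlet", scheme = "quick")
  b <- solve_transport(col, cond, NULL, d_l, time_grid = tg)
  expect_equal(a$value, b$value, tolerance = 1e-8)
})

test_that("extra-column units delay and mix as CSTR + PFR", {
  tg <- seq(0, 600, length.out = 2401)
  step <- chrom_signal(tg, rep(1, length(tg)), "inlet")

  # pure delay: Table-1 volumes at 1 mL/min give (0.025 + 1.753) mL,
  # i.e. 1.778 min
  ec_delay <- extra_column_config(0, 1.753, 0.025)
  out <- extra_column(step, ec_delay, 1)
  t_on <- out$time_s[which(out$value > 0.5)[1]]
  expect_equal(t_on, 1.778 * 60, tolerance = 2e-3)

  # CSTR only: exponential saturation 1 - exp(-F t / V)
  ec_mix <- extra_column_config(0.69, 0, 0)
  out2 <- extra_column(step, ec_mix, 1)
  tau <- 0.69 / (1 / 60)
  expect_equal(out2$value, 1 - exp(-tg / tau), tolerance = 1e-4)

  # mass conservation: delayed + mixed pulse keeps its area
  pulse <- chrom_signal(tg, dnorm(tg, 60, 10), "pulse_response")
  both <- extra_column(pulse, extra_column_config(0.69, 1.753, 0.025), 1)
  area_in <- sum(diff(tg) * (pulse$value[-1] + pulse$value[-2401]) / 2)
  area_out <- sum(diff(tg) * (both$value[-1] + both$value[-2401]) / 2)
  expect_equal(area_out, area_in, tolerance = 1e-3)
})

test_that("simulate_experiment chains feed, system volumes and bed", {
  cfg <- load_config(mchrom_example("table1_run.yaml"))
  cfg$numerics$n_cells <- 120
  cfg$numerics$n_time <- 400
  out <- simulate_experiment(cfg)
  expect_true(all(c("volume_ml", "c_over_c0") %in% names(out)))
  # nothing elutes before the extra-column delay
  delay_s <- v_pfr(cfg$extra_column, 1) / (1 / 60)
  expect_lt(max(out$c_over_c0[out$time_s <= delay_s]), 1e-6)
  # sigmoidal rise to saturation around the (delayed) stoichiometric front
  expect_gt(max(out$c_over_c0), 0.99)
  v <- interstitial_velocity(cfg$column, 1)
  q0 <- equilibrium_loading(cfg$isotherm, 0.48)
  t_front <- cfg$column$L / v *
    (1 + (1 - 0.545) / 0.545 * q0 / 0.48) + delay_s
  expect_lt(max(out$c_over_c0[out$time_s < 0.5 * t_front]), 0.05)

  # zero feed gives a zero outlet
  cfg0 <- cfg
  cfg0$conditions <- operating_conditions(1, 0)
  cfg0$numerics$t_end_s <- 300
  out0 <- simulate_experiment(cfg0)
  expect_true(all(out0$value == 0))
})

test_that("the delta regularization is converged at its default", {
  cfg <- load_config(mchrom_example("table1_run.yaml"))
  cfg$numerics$n_cells <- 120
  cfg$numerics$n_time <- 400
  chk <- delta_convergence_check(cfg)
  expect_lt(chk$relative_change, 0.01)
})
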