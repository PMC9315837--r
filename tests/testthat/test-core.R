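test_that("unit conversions round-trip losslessly", {
  x <- c(0.03, 1, 2, 5, 10, 123.456)
  expect_equal(cm3_s_to_ml_min(ml_min_to_cm3_s(x)), x, tolerance = 1e-14)
  expect_equal(cm_to_um(um_to_cm(x)), x, tolerance = 1e-12)
})

test_that("interstitial velocity follows F/(eps A)", {
  col <- membrane_column(275e-4, diameter_cm = 2.2, porosity = 0.8)
  # hand arithmetic: (1/60) / (0.8 * pi * 1.21)
  expect_equal(interstitial_velocity(col, 1), (1 / 60) / (0.8 * pi * 1.1^2),
               tolerance = 1e-12)
  expect_equal(interstitial_velocity(col, 1), 5.481e-3, tolerance = 1e-3)
  # linear in F
  expect_equal(interstitial_velocity(col, 10),
               10 * interstitial_velocity(col, 1), tolerance = 1e-14)
  # identity case: eps = 1 is not allowed (open tube is not a bed), use
  # the algebraic identity against superficial velocity instead
  expect_equal(superficial_velocity(col, 1) / col$porosity,
               interstitial_velocity(col, 1), tolerance = 1e-14)
})

test_that("v * eps * A * t recovers the fed volume F * t", {
  col <- membrane_column(0.1, area_cm2 = 3.8, porosity = 0.545)
  for (f in c(1, 2, 5, 10)) {
    v <- interstitial_velocity(col, f)
    t <- 123.4
    expect_equal(v * col$porosity * col$A * t, ml_min_to_cm3_s(f) * t,
                 tolerance = 1e-12)
  }
})

test_that("column constructor validates geometry", {
  expect_error(membrane_column(0.1, area_cm2 = 3.8, porosity = 1.2), "porosity")
  expect_error(membrane_column(0.1, area_cm2 = 3.8, porosity = 1), "porosity")
  expect_error(membrane_column(-0.1, area_cm2 = 3.8, porosity = 0.5),
               "thickness_cm")
  expect_error(membrane_column(0.1, porosity = 0.5), "area_cm2")
  # diameter and area disagreeing by more than 0.1%
  expect_error(
    membrane_column(0.1, area_cm2 = 3.9, diameter_cm = 2.2, porosity = 0.5),
    "disagrees"
  )
  # consistent pair: diameter wins, area = pi d^2/4
  col <- membrane_column(0.1, area_cm2 = 3.801, diameter_cm = 2.2,
                         porosity = 0.5)
  expect_equal(col$A, pi * 1.1^2, tolerance = 1e-12)
})

test_that("config loader validates and normalizes a full file", {
  cfg <- load_config(mchrom_example("table1_run.yaml"))
  expect_s3_class(cfg$column, "membrane_column")
  expect_equal(cfg$column$L, 0.1)
  expect_equal(cfg$column$A, 3.8)
  expect_equal(cfg$column$porosity, 0.545)
  expect_equal(cfg$conditions$F, 1 / 60, tolerance = 1e-15)
  expect_equal(cfg$isotherm$q_m, c(4.75, 7.00))
  expect_equal(v_pfr(cfg$extra_column, 1), 1.778)

  psd_cfg <- load_config(mchrom_example("sartobind_psd.yaml"))
  expect_equal(psd_cfg$column$A, pi * 1.1^2, tolerance = 1e-12)
  expect_null(psd_cfg$isotherm)
  expect_equal(psd_cfg$psd$sigma_um, 0.10)
})

test_that("config loader reports offending fields", {
  bad <- tempfile(fileext = ".yaml")
  writeLines(c(
    "column:", "  thickness_cm: 0.1", "  area_cm2: 3.8", "  porosity: 1.2",
    "conditions:", "  flowrate_ml_min: 1"
  ), bad)
  expect_error(load_config(bad), "porosity")

  writeLines(c(
    "column:", "  thickness_cm: 0.1", "  area_cm2: 3.8", "  porosity: 0.5",
    "  bogus_field: 1",
    "conditions:", "  flowrate_ml_min: 1"
  ), bad)
  expect_error(load_config(bad), "bogus_field")

  writeLines("conditions: {flowrate_ml_min: 1}", bad)
  expect_error(load_config(bad), "column")
})

test_that("signals validate their invariants and round-trip through CSV", {
  expect_error(chrom_signal(c(0, 1, 1), c(0, 0, 0)), "increasing")
  expect_error(chrom_signal(c(0, 1), c(0, NA)), "finite")
  expect_error(chrom_signal(0:2, c(0, -1, 0), "pulse_response"),
               "non-negative")

  s <- chrom_signal(seq(0, 10, 0.5), sin(seq(0, 10, 0.5))^2, "pulse_response")
  f <- tempfile(fileext = ".csv")
  write_signal_csv(s, f)
  s2 <- read_signal_csv(f, kind = "pulse_response")
  expect_equal(s2$time_s, s$time_s, tolerance = 1e-11)
  expect_equal(s2$value, s$value, tolerance = 1e-11)
  expect_identical(signal_kind(s2), "pulse_response")
})

test_that("extra-column volumes validate and evaluate", {
  ec <- extra_column_config(0.69, 1.753, 0.025)
  expect_equal(v_pfr(ec, 1), 0.025 * 1 + 1.753)
  expect_equal(v_pfr(ec, 10), 0.025 * 10 + 1.753)
  expect_error(extra_column_config(-1), "v_cstr_ml")
})
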