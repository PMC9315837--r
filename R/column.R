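#' Membrane column geometry
#'
#' Describes a stacked-membrane bed: total thickness `L` (cm), frontal
#' cross-section area `A` (cm^2) and void fraction (porosity) `epsilon`.
#' The area may be given directly or via the disc diameter
#' (`A = pi d^2 / 4`).  If both are supplied they must agree to 0.1%,
#' in which case the diameter wins.
#'
#' @param thickness_cm Bed thickness L in cm (> 0).
#' @param area_cm2 Frontal area A in cm^2, or `NULL` if `diameter_cm` given.
#' @param diameter_cm Disc diameter in cm, or `NULL`.
#' @param porosity Void fraction, strictly between 0 and 1.
#' @param n_layers Number of stacked membrane sheets (informational).
#' @return An object of class `membrane_column` with fields
#'   `L`, `A`, `porosity`, `n_layers`.
#' @examples
#' membrane_column(thickness_cm = 0.1, area_cm2 = 3.8, porosity = 0.545)
#' membrane_column(thickness_cm = 275e-4, diameter_cm = 2.2, porosity = 0.8)
#' @export
membrane_column <- function(thickness_cm, area_cm2 = NULL, diameter_cm = NULL,
                            porosity, n_layers = NA_integer_) {
  check_number(thickness_cm, "thickness_cm", lower = 0)
  check_number(porosity, "porosity", lower = 0, upper = 1)
  if (is.null(area_cm2) && is.null(diameter_cm)) {
    abort_field("area_cm2", "one of `area_cm2` or `diameter_cm` is required")
  }
  if (!is.null(diameter_cm)) {
    check_number(diameter_cm, "diameter_cm", lower = 0)
    a_d <- pi * diameter_cm^2 / 4
    if (!is.null(area_cm2)) {
      check_number(area_cm2, "area_cm2", lower = 0)
      if (abs(a_d - area_cm2) / area_cm2 > 1e-3) {
        abort_field("diameter_cm", sprintf(
          "disagrees with `area_cm2` by more than 0.1%% (%g vs %g cm^2)",
          a_d, area_cm2
        ))
      }
    }
    area_cm2 <- a_d
  } else {
    check_number(area_cm2, "area_cm2", lower = 0)
  }
  structure(
    list(L = thickness_cm, A = area_cm2, porosity = porosity,
         n_layers = n_layers),
    class = "membrane_column"
  )
}

#' @export
print.membrane_column <- function(x, ...) {
  cat(sprintf(
    "<membrane_column> L = %g cm, A = %g cm^2, porosity = %g%s\n",
    x$L, x$A, x$porosity,
    if (is.na(x$n_layers)) "" else sprintf(", %d layers", x$n_layers)
  ))
  invisible(x)
}

#' Operating conditions of a frontal run
#'
#' @param flowrate_ml_min Volumetric flowrate in mL/min (> 0).
#' @param c0_mg_ml Feed concentration in mg/mL (>= 0); defaults to 1
#'   (normalized non-binding tracer).
#' @return An object of class `operating_conditions` with the flowrate
#'   stored in cm^3/s (`F`) and in mL/min (`flowrate_ml_min`).
#' @examples
#' operating_conditions(1, c0_mg_ml = 0.48)
#' @export
operating_conditions <- function(flowrate_ml_min, c0_mg_ml = 1) {
  check_number(flowrate_ml_min, "flowrate_ml_min", lower = 0)
  check_number(c0_mg_ml, "c0_mg_ml", lower = 0, allow_equal_lower = TRUE)
  structure(
    list(F = ml_min_to_cm3_s(flowrate_ml_min),
         flowrate_ml_min = flowrate_ml_min,
         c0 = c0_mg_ml),
    class = "operating_conditions"
  )
}

#' @export
print.operating_conditions <- function(x, ...) {
  cat(sprintf("<operating_conditions> F = %g mL/min, c0 = %g mg/mL\n",
              x$flowrate_ml_min, x$c0))
  invisible(x)
}

#' Velocities in the membrane bed
#'
#' The superficial velocity is `u = F / A`; the interstitial velocity,
#' i.e. the mean velocity in the void space, is `<v> = F / (eps A)`.
#'
#' @param column A [membrane_column()].
#' @param flowrate_ml_min Flowrate in mL/min.
#' @return Velocity in cm/s.
#' @examples
#' col <- membrane_column(275e-4, diameter_cm = 2.2, porosity = 0.8)
#' interstitial_velocity(col, 1) # ~5.48e-3 cm/s
#' @export
interstitial_velocity <- function(column, flowrate_ml_min) {
  stopifnot(inherits(column, "membrane_column"))
  check_number(flowrate_ml_min, "flowrate_ml_min", lower = 0)
  ml_min_to_cm3_s(flowrate_ml_min) / (column$porosity * column$A)
}

#' @rdname interstitial_velocity
#' @export
superficial_velocity <- function(column, flowrate_ml_min) {
  stopifnot(inherits(column, "membrane_column"))
  check_number(flowrate_ml_min, "flowrate_ml_min", lower = 0)
  ml_min_to_cm3_s(flowrate_ml_min) / column$A
}

#' Extra-column volumes
#'
#' Mixing volumes of the chromatographic system outside the membrane bed,
#' modelled as a plug-flow (pure delay) unit of volume `V_pfr(F)` and a
#' continuously-stirred tank of volume `V_cstr`.  The plug-flow volume may
#' depend linearly on the flowrate:
#' `V_pfr(F) = intercept + slope * F[mL/min]`.
#'
#' @param v_cstr_ml CSTR volume, mL (>= 0).
#' @param v_pfr_intercept_ml PFR volume intercept, mL (>= 0).
#' @param v_pfr_slope_ml_per_ml_min PFR volume slope, mL per (mL/min).
#' @return An object of class `extra_column_config`.
#' @examples
#' ec <- extra_column_config(0.69, 1.753, 0.025)
#' v_pfr(ec, 1) # 1.778 mL
#' @export
extra_column_config <- function(v_cstr_ml = 0, v_pfr_intercept_ml = 0,
                                v_pfr_slope_ml_per_ml_min = 0) {
  check_number(v_cstr_ml, "v_cstr_ml", lower = 0, allow_equal_lower = TRUE)
  check_number(v_pfr_intercept_ml, "v_pfr_intercept_ml",
               lower = 0, allow_equal_lower = TRUE)
  check_number(v_pfr_slope_ml_per_ml_min, "v_pfr_slope_ml_per_ml_min",
               lower = 0, allow_equal_lower = TRUE)
  structure(
    list(v_cstr = v_cstr_ml,
         v_pfr_intercept = v_pfr_intercept_ml,
         v_pfr_slope = v_pfr_slope_ml_per_ml_min),
    class = "extra_column_config"
  )
}

#' @rdname extra_column_config
#' @param ec An `extra_column_config`.
#' @param flowrate_ml_min Flowrate in mL/min.
#' @return `v_pfr()`: effective plug-flow volume at that flowrate, mL.
#' @export
v_pfr <- function(ec, flowrate_ml_min) {
  stopifnot(inherits(ec, "extra_column_config"))
  ec$v_pfr_intercept + ec$v_pfr_slope * flowrate_ml_min
}
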