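#' Adsorption isotherms
#'
#' Local-equilibrium adsorption models used inside the transport equation.
#' `q` is expressed per unit volume of solid membrane material, so the
#' `(1 - eps)` factor multiplies `q` in mass balances.
#'
#' A Langmuir isotherm is `q = q_m c / (K_d + c)`.  The bi-Langmuir model
#' is the sum of two such terms, conventionally one irreversible
#' (`K_d = 0`, a step to `q_m` for any c > 0) and one reversible.
#'
#' @param variant `"langmuir"` or `"bi_langmuir"`.
#' @param q_m,k_d Langmuir capacity (mg per mL solid) and dissociation
#'   constant (mg/mL); used when `variant = "langmuir"`.
#' @param q_m_irr,k_d_irr,q_m_rev,k_d_rev Bi-Langmuir site parameters.
#' @return An object of class `isotherm`.
#' @examples
#' iso <- isotherm("bi_langmuir", q_m_irr = 4.75, k_d_irr = 0,
#'                 q_m_rev = 7.00, k_d_rev = 1.15)
#' equilibrium_loading(iso, 1.15) # 4.75 + 7/2 = 8.25
#' @export
isotherm <- function(variant = c("langmuir", "bi_langmuir"),
                     q_m = NULL, k_d = NULL,
                     q_m_irr = NULL, k_d_irr = NULL,
                     q_m_rev = NULL, k_d_rev = NULL) {
  variant <- match.arg(variant)
  if (variant == "langmuir") {
    check_number(q_m, "q_m", lower = 0, allow_equal_lower = TRUE)
    check_number(k_d, "k_d", lower = 0, allow_equal_lower = TRUE)
    qm <- q_m; kd <- k_d
  } else {
    check_number(q_m_irr, "q_m_irr", lower = 0, allow_equal_lower = TRUE)
    check_number(k_d_irr, "k_d_irr", lower = 0, allow_equal_lower = TRUE)
    check_number(q_m_rev, "q_m_rev", lower = 0, allow_equal_lower = TRUE)
    check_number(k_d_rev, "k_d_rev", lower = 0, allow_equal_lower = TRUE)
    qm <- c(q_m_irr, q_m_rev); kd <- c(k_d_irr, k_d_rev)
  }
  # an all-zero isotherm is allowed: it is the non-binding limit and the
  # transport model then reduces to the pure convection-dispersion equation
  structure(list(variant = variant, q_m = qm, k_d = kd), class = "isotherm")
}

#' @export
print.isotherm <- function(x, ...) {
  cat(sprintf("<isotherm> %s\n", x$variant))
  lab <- if (x$variant == "langmuir") "site" else c("irreversible", "reversible")
  for (i in seq_along(x$q_m)) {
    cat(sprintf("  %-12s q_m = %g mg/mL-solid, K_d = %g mg/mL\n",
                lab[i], x$q_m[i], x$k_d[i]))
  }
  invisible(x)
}

#' Equilibrium loading q(c)
#'
#' Evaluates the adsorbed concentration at equilibrium with a liquid-phase
#' concentration `c`.  A site with `K_d = 0` binds irreversibly: its
#' contribution is `q_m` for any `c > 0` and 0 at `c = 0` (a documented
#' discontinuity at the origin).
#'
#' @param iso An [isotherm()].
#' @param c Liquid concentration(s), mg/mL, non-negative.
#' @return Adsorbed concentration(s) q, mg per mL of solid.
#' @export
equilibrium_loading <- function(iso, c) {
  stopifnot(inherits(iso, "isotherm"))
  if (any(!is.finite(c)) || any(c < 0)) {
    abort_field("c", "concentrations must be finite and non-negative")
  }
  q <- numeric(length(c))
  for (i in seq_along(iso$q_m)) {
    if (iso$k_d[i] == 0) {
      q <- q + ifelse(c > 0, iso$q_m[i], 0)
    } else {
      q <- q + iso$q_m[i] * c / (iso$k_d[i] + c)
    }
  }
  q
}

#' Lumped capacity factor of the transport equation
#'
#' The local-equilibrium transport equation can be written with all
#' accumulation lumped on the time derivative:
#' `phi(c) * dc/dt + <v> dc/dz = D_L d2c/dz2` with
#' `phi(c) = 1 + ((1 - eps)/eps) * sum_i q_m,i K_d,i / (c + K_d,i)^2`,
#' i.e. `phi(c) = 1 + ((1 - eps)/eps) * dq/dc`.
#'
#' An irreversible site (`K_d = 0`) makes `dq/dc` a Dirac spike at c = 0.
#' It is regularized by replacing `K_d = 0` with a small `delta`
#' (default 1e-3 mg/mL); convergence in `delta` should be checked by
#' halving it (see the package vignette).
#'
#' @inheritParams equilibrium_loading
#' @param porosity Void fraction of the bed.
#' @param delta Regularization constant, mg/mL, substituted for any
#'   `K_d = 0`.  Must be > 0 if the isotherm has an irreversible site.
#' @return Dimensionless multiplier(s) of dc/dt, always >= 1.
#' @export
capacity_factor <- function(iso, c, porosity, delta = 1e-3) {
  stopifnot(inherits(iso, "isotherm"))
  check_number(porosity, "porosity", lower = 0, upper = 1)
  check_number(delta, "delta", lower = 0, allow_equal_lower = TRUE)
  if (any(!is.finite(c)) || any(c < 0)) {
    abort_field("c", "concentrations must be finite and non-negative")
  }
  kd <- iso$k_d
  if (any(kd == 0)) {
    if (delta == 0) {
      abort_field("delta", paste(
        "must be > 0 to regularize an irreversible site (K_d = 0);",
        "the unregularized derivative is singular at c = 0"
      ))
    }
    kd[kd == 0] <- delta
  }
  dq_dc <- rep(0, length(c))
  for (i in seq_along(iso$q_m)) {
    dq_dc <- dq_dc + iso$q_m[i] * kd[i] / (c + kd[i])^2
  }
  1 + (1 - porosity) / porosity * dq_dc
}

# internal: equilibrium loading with the same delta-regularization as
# capacity_factor, so that PDE mass balances close consistently
equilibrium_loading_reg <- function(iso, c, delta) {
  kd <- iso$k_d
  kd[kd == 0] <- delta
  q <- numeric(length(c))
  for (i in seq_along(iso$q_m)) {
    q <- q + iso$q_m[i] * c / (kd[i] + c)
  }
  q
}
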