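#' Load a simulation configuration
#'
#' Reads a YAML or JSON configuration file and validates every section
#' into the package's domain objects.  Unknown fields raise an error
#' naming the offending field; unit conventions are those of the
#' constructors (mL/min, micrometres, mg/mL), converted internally to CGS.
#'
#' The documented schema (`schema_version: 1`):
#' \preformatted{
#' schema_version: 1
#' column:       {thickness_cm, area_cm2 | diameter_cm, porosity, n_layers}
#' conditions:   {flowrate_ml_min, c0_mg_ml}
#' isotherm:     {variant: langmuir | bi_langmuir, q_m, k_d,
#'                q_m_irr, k_d_irr, q_m_rev, k_d_rev}          # optional
#' psd:          {mu_um, sigma_um, rmin_um, rmax_um, theta, n_bins} # optional
#' extra_column: {v_cstr_ml, v_pfr_intercept_ml,
#'                v_pfr_slope_ml_per_ml_min}                   # optional
#' dispersion:   {alpha_cm | d_l_cm2_s}                        # optional
#' numerics:     {n_cells, rtol, atol, delta_mg_ml, n_time, t_end_s,
#'                breakthrough_n_time, extend}                 # optional
#' moments:      {epsilon_in_moments}                              # optional
#' }
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of class `mchrom_config` with validated elements
#'   `column`, `conditions`, and optionally `isotherm`, `psd` (kept as the
#'   raw parameter list, discretized on demand), `extra_column`,
#'   `dispersion`, `numerics`, `moments`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort_field("path", paste("no such file:", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("schema_version", "column", "conditions", "isotherm", "psd",
             "extra_column", "dispersion", "numerics", "moments")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    abort_field(extra[1], "unknown configuration section")
  }
  sv <- raw$schema_version %||% 1
  if (!identical(as.numeric(sv), 1)) {
    abort_field("schema_version", "only version 1 is supported")
  }
  if (is.null(raw$column)) abort_field("column", "section is required")
  if (is.null(raw$conditions)) abort_field("conditions", "section is required")

  take <- function(section, fields, where) {
    extra <- setdiff(names(section), fields)
    if (length(extra)) {
      abort_field(paste0(where, ".", extra[1]), "unknown field")
    }
    section
  }

  colr <- take(raw$column,
               c("thickness_cm", "area_cm2", "diameter_cm", "porosity",
                 "n_layers"), "column")
  column <- membrane_column(
    thickness_cm = colr$thickness_cm,
    area_cm2 = colr$area_cm2, diameter_cm = colr$diameter_cm,
    porosity = colr$porosity,
    n_layers = colr$n_layers %||% NA_integer_
  )

  cndr <- take(raw$conditions, c("flowrate_ml_min", "c0_mg_ml"), "conditions")
  conditions <- operating_conditions(
    flowrate_ml_min = cndr$flowrate_ml_min,
    c0_mg_ml = cndr$c0_mg_ml %||% 1
  )

  iso <- NULL
  if (!is.null(raw$isotherm)) {
    ir <- take(raw$isotherm,
               c("variant", "q_m", "k_d", "q_m_irr", "k_d_irr",
                 "q_m_rev", "k_d_rev"), "isotherm")
    iso <- isotherm(
      variant = ir$variant %||% "langmuir",
      q_m = ir$q_m, k_d = ir$k_d,
      q_m_irr = ir$q_m_irr, k_d_irr = ir$k_d_irr,
      q_m_rev = ir$q_m_rev, k_d_rev = ir$k_d_rev
    )
  }

  psd <- NULL
  if (!is.null(raw$psd)) {
    pr <- take(raw$psd,
               c("mu_um", "sigma_um", "rmin_um", "rmax_um", "theta",
                 "n_bins"), "psd")
    psd <- list(
      mu_um = pr$mu_um, sigma_um = pr$sigma_um,
      rmin_um = pr$rmin_um %||% 0.50, rmax_um = pr$rmax_um %||% 6.50,
      theta = pr$theta %||% 1e-5, n_bins = pr$n_bins %||% 600
    )
    # validate eagerly
    do.call(discretize_psd, psd)
  }

  ec <- NULL
  if (!is.null(raw$extra_column)) {
    er <- take(raw$extra_column,
               c("v_cstr_ml", "v_pfr_intercept_ml",
                 "v_pfr_slope_ml_per_ml_min"), "extra_column")
    ec <- extra_column_config(
      v_cstr_ml = er$v_cstr_ml %||% 0,
      v_pfr_intercept_ml = er$v_pfr_intercept_ml %||% 0,
      v_pfr_slope_ml_per_ml_min = er$v_pfr_slope_ml_per_ml_min %||% 0
    )
  }

  dispersion <- NULL
  if (!is.null(raw$dispersion)) {
    dr <- take(raw$dispersion, c("alpha_cm", "d_l_cm2_s"), "dispersion")
    dispersion <- dr
  }

  numerics <- raw$numerics %||% list()
  take(numerics, c("n_cells", "rtol", "atol", "delta_mg_ml", "n_time",
                   "t_end_s", "breakthrough_n_time", "extend"), "numerics")
  moments <- raw$moments %||% list()
  take(moments, "epsilon_in_moments", "moments")

  structure(
    list(column = column, conditions = conditions, isotherm = iso,
         psd = psd, extra_column = ec, dispersion = dispersion,
         numerics = numerics, moments = moments),
    class = "mchrom_config"
  )
}

#' Path to a bundled example configuration
#'
#' @param name File name under the package's `extdata/` directory; with no
#'   argument, lists the available files.
#' @return A file path, or a character vector of available names.
#' @export
mchrom_example <- function(name = NULL) {
  if (is.null(name)) {
    dir(system.file("extdata", package = "mchrom"))
  } else {
    p <- system.file("extdata", name, package = "mchrom")
    if (p == "") abort_field("name", paste("no bundled file", name))
    p
  }
}
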