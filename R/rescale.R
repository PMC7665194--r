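# Rescaling structural and functional measurements to percent of mean normal,
# the common scale on which the two components are modelled jointly.

#' Mean normal values used for rescaling
#'
#' Container for the healthy-cohort mean of each parameter. The defaults are
#' the published normative means: rim area 1.44 mm^2, RNFL thickness
#' 98.47 um, linearized MD 1.06 1/L, linearized 30-2 MS 972.60 1/L. The
#' linear-domain values are the primary stored normals; their decibel
#' counterparts are annotations only. Sectoral rim-area/MS normals have no
#' published defaults and must be supplied explicitly when sectoral series
#' are rescaled.
#'
#' @param ra_mm2 Mean normal neuroretinal rim area, mm^2.
#' @param rnflt_um Mean normal retinal nerve fiber layer thickness, um.
#' @param md_linear Mean normal linearized mean deviation, 1/Lambert.
#' @param ms_linear Mean normal linearized mean sensitivity, 1/Lambert.
#' @param sectors Optional named list of per-sector normals, each a list with
#'   elements `ra_mm2` and/or `ms_linear` (no defaults supplied).
#' @return A `mean_normals` object.
#' @export
mean_normals <- function(ra_mm2 = 1.44, rnflt_um = 98.47,
                         md_linear = 1.06, ms_linear = 972.60,
                         sectors = NULL) {
  vals <- c(ra_mm2 = ra_mm2, rnflt_um = rnflt_um,
            md_linear = md_linear, ms_linear = ms_linear)
  check_finite(vals, "mean normals")
  if (any(vals <= 0)) stop_dsf("mean normal values must be strictly positive")
  structure(list(ra_mm2 = ra_mm2, rnflt_um = rnflt_um,
                 md_linear = md_linear, ms_linear = ms_linear,
                 sectors = sectors),
            class = "mean_normals")
}

#' Linearize a mean deviation value
#'
#' MD in decibels (possibly negative in glaucoma) is mapped to linear units
#' as `10^(MD/10)`, the transform conventionally applied to deviation values
#' before averaging or rescaling.
#'
#' @param md_db Numeric vector of MD values in dB.
#' @return Linearized MD, 1/Lambert.
#' @export
md_to_linear <- function(md_db) db_to_linear(md_db)

#' Express a measurement as percent of mean normal
#'
#' `100 * value / normal`, with the normal drawn from a [mean_normals()]
#' object by parameter name. A healthy measurement maps to about 100%; the
#' mean normal itself maps to exactly 100%.
#'
#' @param value Numeric vector; raw measurement. Rim area and RNFLT must be
#'   positive; linearized indices must be non-negative.
#' @param parameter One of `"RA"`, `"RNFLT"`, `"MD_linear"`, `"MS_linear"`.
#' @param normals A [mean_normals()] object.
#' @return Percent of mean normal.
#' @examples
#' nm <- mean_normals()
#' to_percent_mean_normal(1.05, "RA", nm)                 # 72.9
#' to_percent_mean_normal(db_to_linear(28), "MS_linear", nm)  # 64.9
#' @export
to_percent_mean_normal <- function(value,
                                   parameter = c("RA", "RNFLT", "MD_linear",
                                                 "MS_linear"),
                                   normals = mean_normals()) {
  parameter <- match.arg(parameter)
  if (!inherits(normals, "mean_normals")) {
    stop_dsf("`normals` must be a mean_normals object")
  }
  check_finite(value, "value")
  normal <- switch(parameter,
                   RA = normals$ra_mm2,
                   RNFLT = normals$rnflt_um,
                   MD_linear = normals$md_linear,
                   MS_linear = normals$ms_linear)
  strict <- parameter %in% c("RA", "RNFLT")
  if (any(if (strict) value <= 0 else value < 0)) {
    stop_dsf(sprintf("`value` out of range for parameter %s", parameter))
  }
  100 * value / normal
}

#' Build a paired structure-function series in percent of mean normal
#'
#' Composes the unit conversions for one eye: the functional input, if given
#' in dB, is linearized with `10^(dB/10)`, then both components are expressed
#' as percent of their mean normal. The result is the time-ordered series of
#' paired points on which the predictors operate.
#'
#' @param structural_values Raw structural measurements (mm^2 for `RA_MS`,
#'   um for `RNFLT_MD`).
#' @param functional_values Functional measurements; dB by default.
#' @param times Visit times in years from baseline, strictly increasing,
#'   non-negative.
#' @param parameter_pair `"RA_MS"` or `"RNFLT_MD"`.
#' @param normals A [mean_normals()] object.
#' @param functional_in_db Set `FALSE` if the functional input is already in
#'   linear 1/Lambert units.
#' @return An `sf_series` data frame with columns `t`, `f_pct`, `s_pct`.
#' @export
make_sf_series <- function(structural_values, functional_values, times,
                           parameter_pair = c("RA_MS", "RNFLT_MD"),
                           normals = mean_normals(),
                           functional_in_db = TRUE) {
  parameter_pair <- match.arg(parameter_pair)
  n <- length(times)
  if (n < 1) stop_dsf("empty series")
  if (length(structural_values) != n || length(functional_values) != n) {
    stop_dsf("structural, functional and time vectors must have equal length")
  }
  check_times(times)
  check_finite(structural_values, "structural_values")
  check_finite(functional_values, "functional_values")
  f_lin <- if (functional_in_db) db_to_linear(functional_values)
           else functional_values
  if (parameter_pair == "RA_MS") {
    s_pct <- to_percent_mean_normal(structural_values, "RA", normals)
    f_pct <- to_percent_mean_normal(f_lin, "MS_linear", normals)
  } else {
    s_pct <- to_percent_mean_normal(structural_values, "RNFLT", normals)
    f_pct <- to_percent_mean_normal(f_lin, "MD_linear", normals)
  }
  structure(data.frame(t = as.numeric(times), f_pct = f_pct, s_pct = s_pct),
            parameter_pair = parameter_pair,
            class = c("sf_series", "data.frame"))
}

as_sf_series <- function(x) {
  if (!is.data.frame(x) || !all(c("t", "f_pct", "s_pct") %in% names(x))) {
    stop_dsf("series must have columns t, f_pct, s_pct")
  }
  check_times(x$t)
  check_finite(x$f_pct, "f_pct")
  check_finite(x$s_pct, "s_pct")
  x
}
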