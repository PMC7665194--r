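# Static automated perimetry (SAP) test-pattern geometry and linear-domain
# mean sensitivity.
#
# The 30-2 and 24-2 Humphrey patterns are shipped as explicit coordinate
# tables (inst/extdata/grid_*_od.tsv) in right-eye (OD) orientation with
# temporal-positive x and superior-positive y, both in degrees of visual-field
# eccentricity on the standard 6-degree grid. Shipping fixtures rather than a
# radius rule keeps the point counts (76 / 54, and 74 / 52 after blind-spot
# removal) directly assertable. Garway-Heath optic-disc sector labels are
# carried on the 52 non-blind-spot 24-2 points; the central/temporal sector
# holds exactly 16 points.

GH_SECTORS <- c("IT", "ST", "T", "IN", "SN", "N")

#' Load a SAP test-pattern point set
#'
#' Returns the fixed geometry of a Humphrey 30-2 or 24-2 test pattern: point
#' coordinates in degrees (temporal-positive x for a right eye,
#' superior-positive y), blind-spot flags for the two points straddling the
#' physiologic blind spot at (15, +/-3) degrees temporal, a flag marking the
#' 24-2 subset of the 30-2 pattern, and Garway-Heath optic-disc sector labels
#' (`IT`, `ST`, `T`, `IN`, `SN`, `N`, or `"none"`). Left eyes are returned as
#' the mirror image of the right-eye table about the vertical midline, with
#' rows re-indexed in chart order (superior rows first, nasal to temporal).
#'
#' @param pattern_id `"30-2"` (76 points) or `"24-2"` (54 points).
#' @param eye `"OD"` (right) or `"OS"` (left).
#' @return A `test_point_set`: a data frame with columns `index`, `x_deg`,
#'   `y_deg`, `blind_spot`, `gh_sector`, `in_24_2` and attributes
#'   `pattern_id` and `eye`.
#' @examples
#' g <- load_grid("24-2", "OD")
#' nrow(g)                       # 54
#' sum(!g$blind_spot)            # 52
#' sum(g$gh_sector == "T")       # 16 central points
#' @export
load_grid <- function(pattern_id = c("30-2", "24-2"), eye = c("OD", "OS")) {
  pattern_id <- match.arg(pattern_id)
  eye <- match.arg(eye)
  file <- system.file("extdata",
                      paste0("grid_", gsub("-", "_", pattern_id), "_od.tsv"),
                      package = "dsfprog", mustWork = TRUE)
  g <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (eye == "OS") {
    g$x_deg <- -g$x_deg
    g <- g[order(-g$y_deg, g$x_deg), ]
    g$index <- seq_len(nrow(g))
    rownames(g) <- NULL
  }
  structure(g, pattern_id = pattern_id, eye = eye,
            class = c("test_point_set", "data.frame"))
}

#' Convert decibel sensitivity to linear (1/Lambert) units
#'
#' SAP threshold sensitivities and mean deviation are reported in decibels;
#' averaging is done in the linear domain, `10^(dB/10)`. 28 dB maps to
#' 630.96 1/L, 0 dB to 1 1/L.
#'
#' @param value_db Numeric vector of decibel values (may be negative).
#' @return Linear sensitivities, same length.
#' @seealso [linear_to_db()], [md_to_linear()]
#' @export
db_to_linear <- function(value_db) {
  check_finite(value_db, "value_db")
  10^(value_db / 10)
}

#' Convert linear (1/Lambert) sensitivity back to decibels
#'
#' Inverse of [db_to_linear()].
#'
#' @param value_linear Positive numeric vector.
#' @return Decibel values.
#' @export
linear_to_db <- function(value_linear) {
  check_finite(value_linear, "value_linear")
  if (any(value_linear <= 0)) stop_dsf("linear sensitivity must be positive")
  10 * log10(value_linear)
}

#' Construct a pointwise sensitivity field
#'
#' A thin validated container pairing a vector of per-point threshold
#' sensitivities (dB) with the test pattern and eye whose fixture order the
#' values follow.
#'
#' @param values_db Numeric vector, one dB value per pattern point (76 for
#'   30-2, 54 for 24-2), in fixture order.
#' @param pattern_id,eye Passed to [load_grid()].
#' @return A `sensitivity_field` object.
#' @export
sensitivity_field <- function(values_db, pattern_id = c("30-2", "24-2"),
                              eye = c("OD", "OS")) {
  pattern_id <- match.arg(pattern_id)
  eye <- match.arg(eye)
  check_finite(values_db, "values_db")
  n_expect <- if (pattern_id == "30-2") 76L else 54L
  if (length(values_db) != n_expect) {
    stop_dsf(sprintf("pattern %s needs %d values, got %d",
                     pattern_id, n_expect, length(values_db)))
  }
  structure(list(pattern_id = pattern_id, eye = eye,
                 values_db = as.numeric(values_db)),
            class = "sensitivity_field")
}

#' Mean sensitivity of a field in linear units
#'
#' Converts each selected point to 1/Lambert and takes the arithmetic mean.
#' Blind-spot-adjacent points are always excluded, so the global 30-2 mean
#' uses 74 points and the global 24-2 mean uses 52. The 24-2 selections can
#' be taken either from a native 24-2 field or from the 52 shared points of
#' a 30-2 field. Garway-Heath sector selections (`selection = "sector"`)
#' average the points assigned to one optic-disc sector; the central/temporal
#' sector (`"T"`) has 16 points.
#'
#' @param field A [sensitivity_field()].
#' @param selection `"global_30_2"`, `"global_24_2"`, or `"sector"`.
#' @param sector Garway-Heath sector label, required when
#'   `selection = "sector"`: one of `"IT"`, `"ST"`, `"T"`, `"IN"`, `"SN"`,
#'   `"N"`.
#' @return Mean sensitivity in 1/Lambert (scalar).
#' @examples
#' f <- sensitivity_field(rep(28, 76), "30-2", "OD")
#' mean_sensitivity(f, "global_30_2")  # 630.96 1/L
#' @export
mean_sensitivity <- function(field,
                             selection = c("global_30_2", "global_24_2",
                                           "sector"),
                             sector = NULL) {
  if (!inherits(field, "sensitivity_field")) {
    stop_dsf("`field` must be a sensitivity_field")
  }
  selection <- match.arg(selection)
  grid <- load_grid(field$pattern_id, field$eye)
  keep <- !grid$blind_spot
  if (selection == "global_30_2") {
    if (field$pattern_id != "30-2") {
      stop_dsf("global_30_2 selection requires a 30-2 field")
    }
  } else if (selection == "global_24_2") {
    keep <- keep & grid$in_24_2
  } else {
    if (is.null(sector) || !sector %in% GH_SECTORS) {
      stop_dsf("`sector` must be one of: ", paste(GH_SECTORS, collapse = ", "))
    }
    keep <- keep & grid$gh_sector == sector
  }
  if (!any(keep)) stop_dsf("empty point selection")
  mean(db_to_linear(field$values_db[keep]))
}
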