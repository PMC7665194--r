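# The two competing predictors of the next structure-function paired
# measurement: the dynamic structure-function (DSF) model and per-component
# ordinary least squares regression over time (OLSLR).
#
# Both operate on an `sf_series` (columns t, f_pct, s_pct) in percent of
# mean normal. The DSF model summarizes the observed pairs by their centroid
# C (component-wise mean, an estimate of the current disease stage) and a
# velocity vector V (the rate at which the pair is drifting through the 2-D
# structure-function plane), then extrapolates. Two published readings of
# the velocity are carried: the textual "average of all rates of change"
# (default, `velocity_rule = "mean"`) and the displayed bare sum of
# visit-to-visit difference quotients (`"sum"`). Likewise the extrapolation:
# the default anchors the prediction at the centroid's own time,
# P = C + V * (t_target - mean(t)), which reproduces a noiseless line
# exactly; the typeset rule P = C + V / (t_target - t_last) is kept verbatim
# as the `"printed"` variant for auditability, although it is dimensionally
# inconsistent (a rate divided by a time).

#' Fit the DSF state (centroid and velocity) to a paired series
#'
#' @param series An `sf_series` (see [make_sf_series()]) or any data frame
#'   with columns `t` (years, strictly increasing), `f_pct`, `s_pct`.
#'   At least 2 visits are required to define a velocity; the evaluation
#'   pipeline only ever fits 3 or more.
#' @param velocity_rule `"mean"` (default): velocity is the average of the
#'   successive difference quotients `(X[i+1] - X[i]) / (t[i+1] - t[i])`;
#'   `"sum"`: the bare sum of those quotients.
#' @return A `dsf_state` with elements `centroid` (named c(f, s)), `velocity`
#'   (same shape, percent per year under `"mean"`), `centroid_time`,
#'   `t_last`, `n_used`, `velocity_rule`.
#' @examples
#' s <- data.frame(t = 0:3, f_pct = c(100, 90, 80, 70),
#'                 s_pct = c(100, 90, 80, 70))
#' st <- dsf_fit(s)
#' st$centroid   # (85, 85)
#' st$velocity   # (-10, -10) per year
#' @export
dsf_fit <- function(series, velocity_rule = c("mean", "sum")) {
  velocity_rule <- match.arg(velocity_rule)
  series <- as_sf_series(series)
  n <- nrow(series)
  if (n < 2) stop_dsf("DSF fit needs at least 2 visits")
  dt <- diff(series$t)
  quot <- cbind(f = diff(series$f_pct) / dt, s = diff(series$s_pct) / dt)
  v <- colSums(quot)
  if (velocity_rule == "mean") v <- v / (n - 1)
  structure(list(
    centroid = c(f = mean(series$f_pct), s = mean(series$s_pct)),
    velocity = c(f = unname(v["f"]), s = unname(v["s"])),
    centroid_time = mean(series$t),
    t_last = series$t[n],
    n_used = n,
    velocity_rule = velocity_rule
  ), class = "dsf_state")
}

#' Predict a future paired measurement from a DSF state
#'
#' @param state A [dsf_fit()] result.
#' @param target_time Target visit time in years; must lie beyond the last
#'   fitted visit.
#' @param rule `"centroid_anchored"` (default):
#'   `P = C + V * (target_time - centroid_time)`; `"printed"`:
#'   `P = C + V / (target_time - t_last)`, the formula exactly as typeset.
#' @return An `sf_prediction` data frame row: `model`, `target_time`,
#'   `f_pct`, `s_pct`, plus the variant labels.
#' @export
dsf_predict <- function(state, target_time,
                        rule = c("centroid_anchored", "printed")) {
  rule <- match.arg(rule)
  if (!inherits(state, "dsf_state")) stop_dsf("`state` must be a dsf_state")
  check_finite(target_time, "target_time")
  if (target_time <= state$t_last) {
    stop_dsf("`target_time` must lie beyond the fitted series")
  }
  p <- if (rule == "centroid_anchored") {
    state$centroid + state$velocity * (target_time - state$centroid_time)
  } else {
    state$centroid + state$velocity / (target_time - state$t_last)
  }
  structure(data.frame(model = "DSF", target_time = target_time,
                       f_pct = unname(p["f"]), s_pct = unname(p["s"]),
                       velocity_rule = state$velocity_rule,
                       prediction_rule = rule,
                       stringsAsFactors = FALSE),
            class = c("sf_prediction", "data.frame"))
}

#' Predict a future paired measurement by per-component least squares
#'
#' Fits an ordinary least squares line against time independently to the
#' functional and structural components and evaluates both fitted lines at
#' the target time.
#'
#' @inheritParams dsf_fit
#' @param target_time Target visit time in years, beyond the fitted series.
#' @return An `sf_prediction` row with `model = "OLSLR"`.
#' @export
olslr_predict <- function(series, target_time) {
  series <- as_sf_series(series)
  if (nrow(series) < 2) stop_dsf("OLSLR needs at least 2 visits")
  check_finite(target_time, "target_time")
  if (target_time <= series$t[nrow(series)]) {
    stop_dsf("`target_time` must lie beyond the fitted series")
  }
  newd <- data.frame(t = target_time)
  f_hat <- unname(stats::predict(stats::lm(f_pct ~ t, data = series), newd))
  s_hat <- unname(stats::predict(stats::lm(s_pct ~ t, data = series), newd))
  structure(data.frame(model = "OLSLR", target_time = target_time,
                       f_pct = f_hat, s_pct = s_hat,
                       velocity_rule = NA_character_,
                       prediction_rule = NA_character_,
                       stringsAsFactors = FALSE),
            class = c("sf_prediction", "data.frame"))
}

#' @export
print.dsf_state <- function(x, ...) {
  cat(sprintf(
    "DSF state (n = %d visits, velocity rule = %s)\n", x$n_used,
    x$velocity_rule))
  cat(sprintf("  centroid: (f = %.2f, s = %.2f) %% of mean normal at t = %.2f y\n",
              x$centroid["f"], x$centroid["s"], x$centroid_time))
  cat(sprintf("  velocity: (f = %.2f, s = %.2f) %%/y\n",
              x$velocity["f"], x$velocity["s"]))
  invisible(x)
}
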