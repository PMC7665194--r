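# Prediction-error evaluation protocol: walk each eye forward from visit 4
# to visit 7, predicting each visit from all preceding ones with both models,
# then compare the per-visit prediction-error distributions.

#' Prediction error of a paired prediction
#'
#' Euclidean distance between the predicted and observed structure-function
#' pair in percent-of-mean-normal space: the square root of the sum of the
#' squared per-component differences.
#'
#' @param predicted,observed Length-2 numeric vectors `(f_pct, s_pct)`, or
#'   `sf_prediction` rows.
#' @return Non-negative scalar, percent of mean normal.
#' @examples
#' prediction_error(c(3, 4), c(0, 0))  # 5
#' @export
prediction_error <- function(predicted, observed) {
  as_pair <- function(x) {
    if (inherits(x, "sf_prediction")) x <- c(x$f_pct, x$s_pct)
    x <- as.numeric(x)
    if (length(x) != 2) stop_dsf("a structure-function pair has 2 components")
    check_finite(x, "pair")
    x
  }
  sqrt(sum((as_pair(predicted) - as_pair(observed))^2))
}

#' Run the visits-4-to-7 prediction experiment on a cohort
#'
#' For every eye, every target visit and every model, fits the model to all
#' visits preceding the target and predicts the paired measurement at the
#' target visit's time; records the prediction, the observed pair, and the
#' prediction error. Every eye must have at least `max(visits)` QC-passed
#' visits — an eye with fewer reaching this stage is an error, since quality
#' control is expected to have removed it.
#'
#' @param cohort A list of `eye_series` objects (see [assemble_series()]),
#'   each a list with `eye_id`, `subgroup` and `series` (an `sf_series` with
#'   at least 7 rows).
#' @param models Character subset of `c("DSF", "OLSLR")`.
#' @param visits Integer target visits, default `4:7` (1-based visit index).
#' @param velocity_rule,prediction_rule DSF variant flags, echoed into the
#'   output; see [dsf_fit()] and [dsf_predict()].
#' @return A `prediction_rows` data frame: `eye_id`, `subgroup`,
#'   `target_visit`, `model`, `f_pred`, `s_pred`, `f_obs`, `s_obs`, `pe`,
#'   `velocity_rule`, `prediction_rule`; one row per (eye, visit, model).
#' @export
run_experiment <- function(cohort, models = c("DSF", "OLSLR"), visits = 4:7,
                           velocity_rule = c("mean", "sum"),
                           prediction_rule = c("centroid_anchored",
                                               "printed")) {
  velocity_rule <- match.arg(velocity_rule)
  prediction_rule <- match.arg(prediction_rule)
  models <- match.arg(models, several.ok = TRUE)
  visits <- as.integer(visits)
  if (length(visits) < 1 || any(visits < 2)) {
    stop_dsf("target visits must be >= 2")
  }
  out <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    eye <- cohort[[i]]
    series <- as_sf_series(eye$series)
    if (nrow(series) < max(visits)) {
      stop_dsf(sprintf(
        "eye %s has %d visits but visit %d is a prediction target; QC should have removed it",
        eye$eye_id, nrow(series), max(visits)))
    }
    rows <- list()
    for (v in visits) {
      train <- series[seq_len(v - 1L), , drop = FALSE]
      t_v <- series$t[v]
      obs <- c(series$f_pct[v], series$s_pct[v])
      for (m in models) {
        p <- if (m == "DSF") {
          dsf_predict(dsf_fit(train, velocity_rule), t_v, prediction_rule)
        } else {
          olslr_predict(train, t_v)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          eye_id = eye$eye_id, subgroup = eye$subgroup %||% "unlabelled",
          target_visit = v, model = m,
          f_pred = p$f_pct, s_pred = p$s_pct,
          f_obs = obs[1], s_obs = obs[2],
          pe = prediction_error(c(p$f_pct, p$s_pct), obs),
          velocity_rule = velocity_rule, prediction_rule = prediction_rule,
          stringsAsFactors = FALSE)
      }
    }
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("prediction_rows", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Distribution-free confidence interval for a median
#'
#' Order-statistic (binomial) interval: with `n` observations the interval
#' `(x_(k), x_(n-k+1))` has coverage `1 - 2 * pbinom(k - 1, n, 0.5)`; `k` is
#' chosen as the largest index keeping two-sided coverage at or above
#' `conf_level`.
#'
#' @param x Numeric vector, `n >= 2`.
#' @param conf_level Nominal coverage, default 0.95.
#' @return Named vector `c(lower, upper)`.
#' @export
median_ci <- function(x, conf_level = 0.95) {
  check_finite(x, "x")
  n <- length(x)
  if (n < 2) stop_dsf("median CI needs at least 2 observations")
  sx <- sort(x)
  alpha <- (1 - conf_level) / 2
  k <- stats::qbinom(alpha, n, 0.5)  # pbinom(k - 1, n, 0.5) < alpha
  k <- max(k, 1L)
  c(lower = sx[k], upper = sx[n - k + 1L])
}

wilcoxon_paired_p <- function(a, b, exact_max_n = 25L) {
  d <- a - b
  d <- d[d != 0]  # classic signed-rank: discard zero differences
  n <- length(d)
  if (n < 6) {
    warning("fewer than 6 non-zero paired differences; Wilcoxon p unavailable")
    return(NA_real_)
  }
  use_exact <- n <= exact_max_n && !any(duplicated(abs(d)))
  p <- suppressWarnings(stats::wilcox.test(
    d, mu = 0, alternative = "two.sided",
    exact = use_exact, correct = TRUE))$p.value
  unname(p)
}

#' Compare per-visit prediction-error distributions between models
#'
#' For each target visit (optionally stratified by baseline subgroup), pairs
#' the two models' prediction errors by eye and reports: median PE per model
#' with a distribution-free 95% CI of the median ([median_ci()]); the
#' two-sided paired Wilcoxon signed-rank p-value (zero differences dropped;
#' exact distribution when 25 or fewer untied pairs remain, otherwise the
#' normal approximation with continuity correction); the percent of eyes in
#' which the first model's PE is strictly lower; and a significance flag at
#' `alpha`.
#'
#' @param rows A `prediction_rows` table from [run_experiment()] containing
#'   exactly two models.
#' @param by_subgroup If `TRUE`, also stratify by `subgroup`.
#' @param models Length-2 character: comparison is `models[1]` vs
#'   `models[2]`.
#' @param conf_level CI coverage for the medians.
#' @param alpha Significance level, default 0.05.
#' @return A `visit_comparison` data frame, one row per visit (by subgroup).
#' @export
compare_models <- function(rows, by_subgroup = FALSE,
                           models = c("DSF", "OLSLR"),
                           conf_level = 0.95, alpha = 0.05) {
  if (!all(models %in% rows$model) || length(models) != 2) {
    stop_dsf("`rows` must contain both models being compared")
  }
  groups <- if (by_subgroup) split(rows, rows$subgroup) else list(all = rows)
  out <- list()
  for (g in names(groups)) {
    sub <- groups[[g]]
    for (v in sort(unique(sub$target_visit))) {
      a <- sub[sub$target_visit == v & sub$model == models[1], ]
      b <- sub[sub$target_visit == v & sub$model == models[2], ]
      if (nrow(a) != nrow(b) || !setequal(a$eye_id, b$eye_id) ||
          anyDuplicated(a$eye_id) || anyDuplicated(b$eye_id)) {
        stop_dsf(sprintf(
          "unpaired prediction rows at visit %d: each eye needs one PE per model", v))
      }
      b <- b[match(a$eye_id, b$eye_id), ]
      ci_a <- median_ci(a$pe, conf_level)
      ci_b <- median_ci(b$pe, conf_level)
      p <- wilcoxon_paired_p(a$pe, b$pe)
      out[[length(out) + 1L]] <- data.frame(
        subgroup = g, target_visit = v, n_eyes = nrow(a),
        model_a = models[1], model_b = models[2],
        median_pe_a = stats::median(a$pe), median_pe_b = stats::median(b$pe),
        ci_a_lower = ci_a["lower"], ci_a_upper = ci_a["upper"],
        ci_b_lower = ci_b["lower"], ci_b_upper = ci_b["upper"],
        wilcoxon_p = p,
        pct_eyes_a_lower = 100 * mean(a$pe < b$pe),
        significant = !is.na(p) && p < alpha,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("visit_comparison", "data.frame"))
}

#' Bland-Altman limits of agreement
#'
#' Agreement between two paired prediction-error measurements: mean of the
#' differences `a - b` and the 95% limits of agreement,
#' `mean(d) +/- 1.96 * sd(d)`.
#'
#' @param pe_a,pe_b Equal-length paired numeric vectors.
#' @return A `bland_altman` list: `mean_difference`, `loa_low`, `loa_high`,
#'   `sd_difference`, `n`, and the per-pair `means`/`differences` used for
#'   plotting.
#' @export
bland_altman <- function(pe_a, pe_b) {
  check_finite(pe_a, "pe_a")
  check_finite(pe_b, "pe_b")
  if (length(pe_a) != length(pe_b)) stop_dsf("paired arrays differ in length")
  if (length(pe_a) < 2) stop_dsf("Bland-Altman needs at least 2 pairs")
  d <- pe_a - pe_b
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(mean_difference = m,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 sd_difference = s, n = length(d),
                 means = (pe_a + pe_b) / 2, differences = d),
            class = "bland_altman")
}
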