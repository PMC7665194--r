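# Synthetic longitudinal structure-function cohorts with known ground truth.
#
# Each eye follows a linear true trajectory in percent-of-mean-normal space
# (baseline pair + rate pair * time) observed with additive Gaussian
# measurement noise, on a visit schedule of roughly 6-month intervals with
# uniform jitter. Baseline and rate distributions differ by baseline
# subgroup (glaucomatous optic neuropathy alone, glaucomatous visual field
# alone, or both) so that structure-only and function-only damage strata are
# represented; the labels are strata, not a pathophysiology model. A
# configurable fraction of visits is made unreliable by drawing one QC field
# beyond its exclusion threshold.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the follow-up structure of the ocular-hypertension and
#' POAG cohorts the package's evaluation protocol is designed for: 7 visits
#' about 6 months apart (about 3 to 3.5 years of follow-up per eye, fitting
#' comfortably inside a 6.5-year study window), slow linear decline in
#' percent of mean normal, and a subgroup mix of 121:97:175
#' (GON-alone : GVF-alone : both).
#'
#' @param n_eyes Number of eyes.
#' @param n_visits Visits per eye, default 7 (the evaluation protocol needs
#'   at least 7).
#' @param visit_interval_years Mean spacing between visits, default 0.5.
#' @param visit_jitter_years Half-width of the uniform jitter on each gap,
#'   default 1/12 (one month); must stay below `visit_interval_years`.
#' @param parameter_pair `"RA_MS"` or `"RNFLT_MD"`.
#' @param subgroup_mix Named non-negative weights over
#'   `GON_alone`, `GVF_alone`, `both`.
#' @param baseline Named list per subgroup, each `list(f = c(mean, sd),
#'   s = c(mean, sd))` in percent of mean normal. Defaults put the damaged
#'   component near 75% and the spared one near 95%.
#' @param rate_mean,rate_sd Mean and SD of the per-eye true rates of change,
#'   percent of mean normal per year (negative = progression), shared by
#'   both components. Defaults -1.5 and 1.
#' @param noise_sd Named `c(f =, s =)` measurement noise SDs in percent of
#'   mean normal, default 2 each.
#' @param fraction_unreliable Probability that a visit fails one QC rule,
#'   default 0.
#' @param output_mode `"summary_indices"` (structural + functional summary
#'   values) or `"pointwise_30_2"` (additionally emits a 76-point dB field
#'   per visit whose linear-domain 74-point mean equals the visit's MS
#'   exactly; `RA_MS` only).
#' @param point_scatter Spatial heterogeneity of pointwise fields: SD of the
#'   log-normal per-point deviation factors, which are renormalized so the
#'   linear-domain mean over the 74 non-blind-spot points is preserved
#'   exactly. `0` gives flat fields (every point at the same dB value).
#'   Default 0.15.
#' @param normals [mean_normals()] used to convert percent trajectories back
#'   to raw instrument units.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_eyes = 100L, n_visits = 7L,
                             visit_interval_years = 0.5,
                             visit_jitter_years = 1 / 12,
                             parameter_pair = c("RA_MS", "RNFLT_MD"),
                             subgroup_mix = c(GON_alone = 121, GVF_alone = 97,
                                              both = 175),
                             baseline = list(
                               GON_alone = list(f = c(95, 8), s = c(75, 8)),
                               GVF_alone = list(f = c(75, 8), s = c(95, 8)),
                               both      = list(f = c(75, 8), s = c(75, 8))),
                             rate_mean = -1.5, rate_sd = 1,
                             noise_sd = c(f = 2, s = 2),
                             fraction_unreliable = 0,
                             output_mode = c("summary_indices",
                                             "pointwise_30_2"),
                             point_scatter = 0.15,
                             normals = mean_normals()) {
  parameter_pair <- match.arg(parameter_pair)
  output_mode <- match.arg(output_mode)
  if (n_eyes < 0) stop_dsf("`n_eyes` must be non-negative")
  if (n_visits < 1) stop_dsf("`n_visits` must be positive")
  if (visit_interval_years <= 0) stop_dsf("visit interval must be positive")
  if (visit_jitter_years < 0 || visit_jitter_years >= visit_interval_years) {
    stop_dsf("visit jitter must be non-negative and below the interval")
  }
  if (fraction_unreliable < 0 || fraction_unreliable > 1) {
    stop_dsf("`fraction_unreliable` must lie in [0, 1]")
  }
  if (any(noise_sd < 0) || !all(c("f", "s") %in% names(noise_sd))) {
    stop_dsf("`noise_sd` must be a named c(f =, s =) pair of non-negative SDs")
  }
  if (!all(names(subgroup_mix) %in% names(baseline)) || any(subgroup_mix < 0) ||
      sum(subgroup_mix) == 0) {
    stop_dsf("`subgroup_mix` must be non-negative weights over the baseline strata")
  }
  if (output_mode == "pointwise_30_2" && parameter_pair != "RA_MS") {
    stop_dsf("pointwise 30-2 output is defined for the RA_MS pair only")
  }
  if (point_scatter < 0) stop_dsf("`point_scatter` must be non-negative")
  structure(list(n_eyes = as.integer(n_eyes), n_visits = as.integer(n_visits),
                 visit_interval_years = visit_interval_years,
                 visit_jitter_years = visit_jitter_years,
                 parameter_pair = parameter_pair,
                 subgroup_mix = subgroup_mix, baseline = baseline,
                 rate_mean = rate_mean, rate_sd = rate_sd,
                 noise_sd = noise_sd,
                 fraction_unreliable = fraction_unreliable,
                 output_mode = output_mode, point_scatter = point_scatter,
                 normals = normals),
            class = "synthetic_config")
}

empty_visit_table <- function(parameter_pair) {
  data.frame(eye_id = character(0), patient_id = character(0),
             t = numeric(0), structural_value = numeric(0),
             structural_unit = character(0), functional_value = numeric(0),
             functional_unit = character(0), mphsd_um = numeric(0),
             fp_pct = numeric(0), fn_pct = numeric(0), fl_pct = numeric(0),
             oct_signal_db = numeric(0), subgroup = character(0),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws per-eye baselines and rates, builds linear true trajectories in
#' percent of mean normal, adds independent Gaussian noise per visit and
#' component, converts to raw instrument units, and emits QC metadata with
#' the configured unreliable fraction. Fully reproducible under a fixed
#' seed.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer RNG seed.
#' @return A list with `visits` (visit-record table in the dialect
#'   [read_cohort()] documents), `truth` (one row per eye: true baseline
#'   pair, true rate pair, subgroup), `fields` (wide 76-column pointwise dB
#'   table, or `NULL` outside pointwise mode), and `seed`.
#' @export
generate_cohort <- function(config, seed = 1L) {
  if (!inherits(config, "synthetic_config")) {
    stop_dsf("`config` must come from synthetic_config()")
  }
  set.seed(as.integer(seed))
  nm <- config$normals
  ra_ms <- config$parameter_pair == "RA_MS"
  if (config$n_eyes == 0) {
    return(list(visits = empty_visit_table(config$parameter_pair),
                truth = data.frame(eye_id = character(0),
                                   subgroup = character(0),
                                   f0_pct = numeric(0), s0_pct = numeric(0),
                                   rate_f = numeric(0), rate_s = numeric(0),
                                   stringsAsFactors = FALSE),
                fields = NULL, seed = as.integer(seed)))
  }
  mix <- config$subgroup_mix / sum(config$subgroup_mix)
  visits <- vector("list", config$n_eyes)
  fields <- vector("list", config$n_eyes)
  truth <- vector("list", config$n_eyes)
  nv <- config$n_visits
  for (i in seq_len(config$n_eyes)) {
    eye_id <- sprintf("eye%05d", i)
    subgroup <- sample(names(mix), 1, prob = mix)
    base <- config$baseline[[subgroup]]
    f0 <- stats::rnorm(1, base$f[1], base$f[2])
    s0 <- stats::rnorm(1, base$s[1], base$s[2])
    rf <- stats::rnorm(1, config$rate_mean, config$rate_sd)
    rs <- stats::rnorm(1, config$rate_mean, config$rate_sd)
    gaps <- config$visit_interval_years +
      stats::runif(nv - 1, -config$visit_jitter_years,
                   config$visit_jitter_years)
    t <- cumsum(c(0, gaps))
    f_pct <- f0 + rf * t + stats::rnorm(nv, 0, config$noise_sd["f"])
    s_pct <- s0 + rs * t + stats::rnorm(nv, 0, config$noise_sd["s"])
    f_pct <- pmax(f_pct, 1e-3)  # linearized indices cannot go non-positive
    s_pct <- pmax(s_pct, 1e-3)
    if (ra_ms) {
      structural <- s_pct / 100 * nm$ra_mm2
      functional_db <- linear_to_db(f_pct / 100 * nm$ms_linear)
    } else {
      structural <- s_pct / 100 * nm$rnflt_um
      functional_db <- linear_to_db(f_pct / 100 * nm$md_linear)
    }
    bad <- stats::runif(nv) < config$fraction_unreliable
    qc <- data.frame(
      mphsd_um = if (ra_ms) stats::runif(nv, 15, 40) else NA_real_,
      fp_pct = stats::runif(nv, 0, 15), fn_pct = stats::runif(nv, 0, 15),
      fl_pct = stats::runif(nv, 0, 15),
      oct_signal_db = if (ra_ms) NA_real_ else stats::runif(nv, 20, 35))
    rules <- if (ra_ms) c("mphsd_um", "fp_pct", "fn_pct", "fl_pct")
             else c("oct_signal_db", "fp_pct", "fn_pct", "fl_pct")
    for (j in which(bad)) {
      rule <- sample(rules, 1)
      qc[j, rule] <- switch(rule,
                            mphsd_um = stats::runif(1, 55, 90),
                            oct_signal_db = stats::runif(1, 5, 15),
                            stats::runif(1, 40, 90))
    }
    visits[[i]] <- data.frame(
      eye_id = eye_id, patient_id = sprintf("pat%05d", (i + 1L) %/% 2L),
      t = t, structural_value = structural,
      structural_unit = if (ra_ms) "mm2" else "um",
      functional_value = functional_db,
      functional_unit = if (ra_ms) "dB_MS" else "dB_MD",
      mphsd_um = qc$mphsd_um, fp_pct = qc$fp_pct, fn_pct = qc$fn_pct,
      fl_pct = qc$fl_pct, oct_signal_db = qc$oct_signal_db,
      subgroup = subgroup, stringsAsFactors = FALSE)
    if (config$output_mode == "pointwise_30_2") {
      # per-point log-normal deviation factors, renormalized so the linear
      # mean over the 74 non-blind-spot points equals the visit's MS exactly
      bs <- load_grid("30-2", "OD")$blind_spot
      ms_lin <- db_to_linear(functional_db)
      fm <- t(vapply(seq_len(nv), function(j) {
        g <- exp(stats::rnorm(76, 0, config$point_scatter))
        linear_to_db(ms_lin[j] * g / mean(g[!bs]))
      }, numeric(76)))
      colnames(fm) <- sprintf("p%02d", 1:76)
      fields[[i]] <- cbind(data.frame(eye_id = eye_id, t = t,
                                      pattern = "30-2", eye = "OD",
                                      stringsAsFactors = FALSE),
                           as.data.frame(fm))
    }
    truth[[i]] <- data.frame(eye_id = eye_id, subgroup = subgroup,
                             f0_pct = f0, s0_pct = s0,
                             rate_f = rf, rate_s = rs,
                             stringsAsFactors = FALSE)
  }
  list(visits = do.call(rbind, visits),
       truth = do.call(rbind, truth),
       fields = if (config$output_mode == "pointwise_30_2") {
         do.call(rbind, fields)
       },
       seed = as.integer(seed))
}

#' Fit DSF states across a cohort and collect velocities
#'
#' Convenience wrapper: runs [dsf_fit()] on every eye's full series.
#'
#' @param cohort List of `eye_series` (see [assemble_series()]).
#' @param velocity_rule Passed to [dsf_fit()].
#' @return Data frame: `eye_id`, `velocity_f`, `velocity_s`, `n_used`.
#' @export
dsf_fit_cohort <- function(cohort, velocity_rule = c("mean", "sum")) {
  velocity_rule <- match.arg(velocity_rule)
  rows <- lapply(cohort, function(eye) {
    st <- dsf_fit(eye$series, velocity_rule)
    data.frame(eye_id = eye$eye_id,
               velocity_f = unname(st$velocity["f"]),
               velocity_s = unname(st$velocity["s"]),
               n_used = st$n_used, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Velocity recovery report against synthetic ground truth
#'
#' Joins fitted DSF velocities to the generator's true rates and reports
#' per-component bias (mean of estimate minus truth) and RMSE.
#'
#' @param truth Truth table from [generate_cohort()].
#' @param fits Velocity table from [dsf_fit_cohort()].
#' @return Data frame with one row per component: `component`, `bias`,
#'   `rmse`, `n`.
#' @export
recovery_report <- function(truth, fits) {
  m <- match(fits$eye_id, truth$eye_id)
  if (any(is.na(m))) stop_dsf("fitted eyes missing from the truth table")
  err_f <- fits$velocity_f - truth$rate_f[m]
  err_s <- fits$velocity_s - truth$rate_s[m]
  data.frame(component = c("f", "s"),
             bias = c(mean(err_f), mean(err_s)),
             rmse = c(sqrt(mean(err_f^2)), sqrt(mean(err_s^2))),
             n = nrow(fits), stringsAsFactors = FALSE)
}
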