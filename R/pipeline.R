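# End-to-end orchestration: simulate -> QC -> rescale -> predict -> compare,
# with an audit trail on disk. These functions are the package's command
# surface; each stage is also callable on its own.

pkg_version_string <- function() {
  as.character(utils::packageVersion("dsfprog"))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Summarize pointwise fields into per-visit mean sensitivity
#'
#' Collapses a wide table of 30-2 pointwise dB fields (columns `p01`..`p76`
#' in fixture order plus `eye_id`, `t`, `pattern`, `eye`) into one MS value
#' per visit, computed in the linear domain over the requested selection and
#' reported back in dB.
#'
#' @param fields Wide pointwise data frame, one row per (eye, visit).
#' @param selection,sector Passed to [mean_sensitivity()].
#' @return Data frame `eye_id`, `t`, `ms_db`.
#' @export
ms_from_fields <- function(fields, selection = "global_30_2", sector = NULL) {
  pcols <- sprintf("p%02d", 1:76)
  if (!all(c("eye_id", "t", pcols) %in% names(fields))) {
    stop_dsf("pointwise table needs columns eye_id, t, p01..p76")
  }
  ms_db <- vapply(seq_len(nrow(fields)), function(i) {
    fld <- sensitivity_field(as.numeric(fields[i, pcols]),
                             fields$pattern[i] %||% "30-2",
                             fields$eye[i] %||% "OD")
    linear_to_db(mean_sensitivity(fld, selection, sector))
  }, numeric(1))
  data.frame(eye_id = fields$eye_id, t = fields$t, ms_db = ms_db,
             stringsAsFactors = FALSE)
}

#' Simulate a cohort and write it to disk
#'
#' Thin file-based wrapper over [generate_cohort()]: writes `visits.csv`,
#' `truth.csv`, `fields.csv` (pointwise mode only) and `meta.json` (seed,
#' package version, configuration hash) into `dir`. With `n_eyes = 0` the
#' files are empty but schema-valid.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer RNG seed.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the named vector of file paths written.
#' @export
simulate_cohort <- function(config, seed = 1L, dir) {
  cohort <- generate_cohort(config, seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(visits = file.path(dir, "visits.csv"),
             truth = file.path(dir, "truth.csv"),
             meta = file.path(dir, "meta.json"))
  utils::write.csv(cohort$visits, paths["visits"], row.names = FALSE)
  utils::write.csv(cohort$truth, paths["truth"], row.names = FALSE)
  if (!is.null(cohort$fields)) {
    paths["fields"] <- file.path(dir, "fields.csv")
    utils::write.csv(cohort$fields, paths["fields"], row.names = FALSE)
  }
  meta <- list(package_version = pkg_version_string(),
               config_hash = config_hash(config), seed = as.integer(seed),
               n_eyes = config$n_eyes, parameter_pair = config$parameter_pair,
               output_mode = config$output_mode)
  jsonlite::write_json(meta, paths["meta"], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Run the full prediction-error analysis on a cohort
#'
#' Chains quality control, series assembly, the visits-4-to-7 prediction
#' experiment and the per-visit model comparison. When `output_dir` is
#' given, writes the QC audit (`qc_audit.csv`), the prediction table
#' (`predictions.csv`), the comparison (`comparison.csv` and
#' `report.json`, the latter carrying the configuration echo), and a
#' median-PE-per-visit figure (`median_pe.png`).
#'
#' @param visits Visit-record data frame, or path to a cohort CSV
#'   ([read_cohort()] dialect).
#' @param fields Optional wide pointwise 30-2 table (or its path); when
#'   supplied, the functional component is recomputed from the fields via
#'   [ms_from_fields()] with the given `selection`/`sector`.
#' @param parameter_pair `"RA_MS"` or `"RNFLT_MD"`.
#' @param normals,thresholds,velocity_rule,prediction_rule,visits_to_predict
#'   Passed through to the respective stages.
#' @param selection,sector Functional summary taken from pointwise fields.
#' @param by_subgroup Stratify the comparison by baseline subgroup.
#' @param output_dir Optional directory for the audit trail.
#' @return A list: `qc` (the [apply_reliability_filters()] result),
#'   `dropped_eyes`, `cohort` (list of `eye_series`), `predictions`,
#'   `comparison`, `meta`.
#' @export
run_pipeline <- function(visits, fields = NULL,
                         parameter_pair = c("RA_MS", "RNFLT_MD"),
                         normals = mean_normals(),
                         thresholds = qc_thresholds(),
                         velocity_rule = "mean",
                         prediction_rule = "centroid_anchored",
                         visits_to_predict = 4:7,
                         selection = "global_30_2", sector = NULL,
                         by_subgroup = FALSE, output_dir = NULL) {
  parameter_pair <- match.arg(parameter_pair)
  if (is.character(visits)) visits <- read_cohort(visits)
  if (is.character(fields)) fields <- utils::read.csv(fields,
                                                      stringsAsFactors = FALSE)
  if (!is.null(fields)) {
    ms <- ms_from_fields(fields, selection, sector)
    key_v <- paste(visits$eye_id, round(visits$t, 9))
    key_m <- paste(ms$eye_id, round(ms$t, 9))
    m <- match(key_v, key_m)
    if (any(is.na(m))) stop_dsf("pointwise fields missing for some visits")
    visits$functional_value <- ms$ms_db[m]
  }
  qc <- apply_reliability_filters(visits, thresholds, parameter_pair)
  cohort <- assemble_series(qc$kept, normals, parameter_pair)
  if (length(cohort) == 0) stop_dsf("no eye survived quality control")
  predictions <- run_experiment(cohort, visits = visits_to_predict,
                                velocity_rule = velocity_rule,
                                prediction_rule = prediction_rule)
  comparison <- compare_models(predictions, by_subgroup = by_subgroup)
  meta <- list(package_version = pkg_version_string(),
               parameter_pair = parameter_pair,
               velocity_rule = velocity_rule,
               prediction_rule = prediction_rule,
               selection = if (is.null(fields)) NA else selection,
               config_hash = config_hash(list(parameter_pair, thresholds,
                                              velocity_rule, prediction_rule,
                                              visits_to_predict, selection,
                                              sector)),
               n_eyes_analyzed = length(cohort),
               n_visits_excluded = nrow(qc$excluded))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    audit <- rbind(
      cbind(qc$kept, decision = "kept", reason = ""),
      cbind(qc$excluded[, names(qc$kept), drop = FALSE],
            decision = "excluded", reason = qc$excluded$reason))
    utils::write.csv(audit, file.path(output_dir, "qc_audit.csv"),
                     row.names = FALSE)
    utils::write.csv(predictions, file.path(output_dir, "predictions.csv"),
                     row.names = FALSE)
    utils::write.csv(comparison, file.path(output_dir, "comparison.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(meta = meta, comparison = comparison),
                         file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    ggplot2::ggsave(file.path(output_dir, "median_pe.png"),
                    plot_median_pe(comparison), width = 7, height = 4.5,
                    dpi = 150)
  }
  list(qc = qc, dropped_eyes = attr(cohort, "dropped"), cohort = cohort,
       predictions = predictions, comparison = comparison, meta = meta)
}

#' Plot median prediction error per visit
#'
#' Point-and-interval display of the per-visit median PE of each model with
#' its distribution-free 95% CI, the standard summary figure for the
#' visits-4-to-7 protocol.
#'
#' @param comparison A `visit_comparison` table from [compare_models()].
#' @return A ggplot object.
#' @export
plot_median_pe <- function(comparison) {
  long <- rbind(
    data.frame(target_visit = comparison$target_visit,
               subgroup = comparison$subgroup,
               model = comparison$model_a, median_pe = comparison$median_pe_a,
               lower = comparison$ci_a_lower, upper = comparison$ci_a_upper),
    data.frame(target_visit = comparison$target_visit,
               subgroup = comparison$subgroup,
               model = comparison$model_b, median_pe = comparison$median_pe_b,
               lower = comparison$ci_b_lower, upper = comparison$ci_b_upper))
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$target_visit), y = .data$median_pe,
    colour = .data$model, group = .data$model)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      position = ggplot2::position_dodge(width = 0.35)) +
    ggplot2::labs(x = "Target visit", y = "Median PE (% of mean normal)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (length(unique(long$subgroup)) > 1) {
    p <- p + ggplot2::facet_wrap(~subgroup)
  }
  p
}

#' Bland-Altman agreement plot
#'
#' @param ba A [bland_altman()] result.
#' @return A ggplot object: per-pair differences against means, the mean
#'   difference (dashed) and the 95% limits of agreement (solid).
#' @export
plot_bland_altman <- function(ba) {
  if (!inherits(ba, "bland_altman")) stop_dsf("`ba` must be a bland_altman")
  df <- data.frame(mean = ba$means, difference = ba$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ba$mean_difference, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high)) +
    ggplot2::labs(x = "Mean PE (% of mean normal)",
                  y = "Difference in PE (% of mean normal)") +
    ggplot2::theme_minimal()
}

#' Read a pipeline configuration from YAML
#'
#' Optional convenience for scripted runs: reads a YAML block with any of
#' the [run_pipeline()] / [synthetic_config()] fields and returns it as a
#' list; unknown keys are rejected so typos do not silently fall back to
#' defaults.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_dsf("reading YAML configs requires the yaml package")
  }
  cfg <- yaml::read_yaml(path)
  known <- c("parameter_pair", "velocity_rule", "prediction_rule",
             "visits_to_predict", "selection", "sector", "by_subgroup",
             "normals", "thresholds", "synthetic", "seed", "paths")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop_dsf("unknown config keys: ", paste(bad, collapse = ", "))
  cfg
}
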