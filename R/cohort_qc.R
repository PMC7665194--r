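# Cohort assembly and reliability-based quality control.
#
# Visit-level exclusion rules, strict inequalities as published:
#   * HRT image unreliable when mean pixel height SD exceeds 50 um;
#   * visual field unreliable when false positives, false negatives or
#     fixation losses exceed 33%;
#   * OCT scan usable only when signal strength exceeds 15 dB.
# Boundary values (exactly 50 um, exactly 33%, strictly above 15 dB) are
# kept. Eligibility is then enforced per eye: at least 7 reliable visits
# with at least 3 months (0.25 y) between consecutive visits; eyes violating
# either rule are dropped whole rather than thinned.

#' Reliability thresholds for visit-level quality control
#'
#' @param mphsd_max_um Maximum acceptable HRT mean pixel height standard
#'   deviation; visits strictly above are excluded. Default 50.
#' @param vf_max_pct Maximum acceptable false-positive, false-negative and
#'   fixation-loss rates (percent); strictly above excludes. Default 33.
#' @param oct_min_signal_db Minimum usable OCT signal strength; a visit is
#'   kept only when signal strength is strictly greater. Default 15.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(mphsd_max_um = 50, vf_max_pct = 33,
                          oct_min_signal_db = 15) {
  check_finite(c(mphsd_max_um, vf_max_pct, oct_min_signal_db), "thresholds")
  structure(list(mphsd_max_um = mphsd_max_um, vf_max_pct = vf_max_pct,
                 oct_min_signal_db = oct_min_signal_db),
            class = "qc_thresholds")
}

qc_fields_for <- function(parameter_pair) {
  structural <- if (parameter_pair == "RA_MS") "mphsd_um" else "oct_signal_db"
  c(structural, "fp_pct", "fn_pct", "fl_pct")
}

#' Apply visit-level reliability filters
#'
#' Partitions visit records into kept and excluded sets. Which QC fields are
#' required follows the measurement modality of the parameter pair: HRT rim
#' area needs `mphsd_um`, OCT RNFL thickness needs `oct_signal_db`, and both
#' pairs need the perimetric reliability indices `fp_pct`, `fn_pct`,
#' `fl_pct`. A record missing a required field is excluded with reason
#' `"missing_qc"`; otherwise every violated rule is recorded (separated by
#' `;` when several fail at once).
#'
#' @param records Data frame of visit records, one row per (eye, visit);
#'   see [read_cohort()] for the column dictionary.
#' @param thresholds A [qc_thresholds()] object.
#' @param parameter_pair `"RA_MS"` (HRT + SAP) or `"RNFLT_MD"` (OCT + SAP).
#' @return A `qc_result` list with elements `kept` (records) and `excluded`
#'   (records plus a `reason` column); the two partition the input exactly.
#' @export
apply_reliability_filters <- function(records,
                                      thresholds = qc_thresholds(),
                                      parameter_pair = c("RA_MS",
                                                         "RNFLT_MD")) {
  parameter_pair <- match.arg(parameter_pair)
  if (!inherits(thresholds, "qc_thresholds")) {
    stop_dsf("`thresholds` must come from qc_thresholds()")
  }
  required <- qc_fields_for(parameter_pair)
  missing_cols <- setdiff(required, names(records))
  for (col in missing_cols) records[[col]] <- NA_real_
  n <- nrow(records)
  reason <- character(n)
  for (i in seq_len(n)) {
    vals <- as.numeric(records[i, required])
    if (any(is.na(vals))) {
      reason[i] <- "missing_qc"
      next
    }
    hit <- character(0)
    if (parameter_pair == "RA_MS") {
      if (records$mphsd_um[i] > thresholds$mphsd_max_um) hit <- c(hit, "mphsd")
    } else {
      if (records$oct_signal_db[i] <= thresholds$oct_min_signal_db) {
        hit <- c(hit, "oct_signal")
      }
    }
    if (records$fp_pct[i] > thresholds$vf_max_pct) hit <- c(hit, "fp")
    if (records$fn_pct[i] > thresholds$vf_max_pct) hit <- c(hit, "fn")
    if (records$fl_pct[i] > thresholds$vf_max_pct) hit <- c(hit, "fl")
    reason[i] <- paste(hit, collapse = ";")
  }
  keep <- reason == ""
  excluded <- records[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  rownames(excluded) <- NULL
  kept <- records[keep, , drop = FALSE]
  rownames(kept) <- NULL
  structure(list(kept = kept, excluded = excluded,
                 thresholds = thresholds, parameter_pair = parameter_pair),
            class = "qc_result")
}

#' Assemble per-eye analysis series from QC-passed visit records
#'
#' Groups reliable visit records by eye, enforces the eligibility rules
#' (at least `min_visits` visits; every consecutive gap at least
#' `min_gap_years`), and rescales each surviving eye's measurements to a
#' percent-of-mean-normal `sf_series` via [make_sf_series()]. Eyes failing
#' eligibility are dropped whole; the dropped set and reasons are attached
#' as the `"dropped"` attribute.
#'
#' @param kept_records Data frame of QC-passed visit records (the `kept`
#'   element of [apply_reliability_filters()]).
#' @param normals A [mean_normals()] object.
#' @param parameter_pair `"RA_MS"` or `"RNFLT_MD"`.
#' @param min_visits Minimum reliable visits per eye, default 7.
#' @param min_gap_years Minimum spacing between consecutive visits in years,
#'   default 0.25 (3 months).
#' @return List of `eye_series` objects (`eye_id`, `patient_id`, `subgroup`,
#'   `records`, `series`), with attribute `dropped`: a data frame of
#'   (eye_id, reason).
#' @export
assemble_series <- function(kept_records, normals = mean_normals(),
                            parameter_pair = c("RA_MS", "RNFLT_MD"),
                            min_visits = 7L, min_gap_years = 0.25) {
  parameter_pair <- match.arg(parameter_pair)
  needed <- c("eye_id", "t", "structural_value", "functional_value")
  missing_cols <- setdiff(needed, names(kept_records))
  if (length(missing_cols)) {
    stop_dsf("records lack columns: ", paste(missing_cols, collapse = ", "))
  }
  eyes <- split(kept_records, kept_records$eye_id)
  out <- list()
  dropped <- list()
  for (id in names(eyes)) {
    rec <- eyes[[id]]
    rec <- rec[order(rec$t), , drop = FALSE]
    if (anyDuplicated(rec$t)) {
      stop_dsf(sprintf("duplicate visit times for eye %s", id))
    }
    if (nrow(rec) < min_visits) {
      dropped[[id]] <- "too_few_visits"
      next
    }
    if (any(diff(rec$t) < min_gap_years)) {
      dropped[[id]] <- "visit_spacing"
      next
    }
    series <- make_sf_series(rec$structural_value, rec$functional_value,
                             rec$t, parameter_pair, normals,
                             functional_in_db = TRUE)
    out[[length(out) + 1L]] <- structure(list(
      eye_id = id,
      patient_id = rec$patient_id[1] %||% NA_character_,
      subgroup = rec$subgroup[1] %||% "unlabelled",
      records = rec, series = series), class = "eye_series")
  }
  dropped_df <- if (length(dropped)) {
    data.frame(eye_id = names(dropped), reason = unlist(dropped),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(eye_id = character(0), reason = character(0))
  }
  structure(out, dropped = dropped_df)
}

#' Read a longitudinal cohort CSV
#'
#' Long format, one row per (eye, visit). Required columns: `eye_id`, `t`
#' (years from baseline), `structural_value`, `functional_value` (dB).
#' Recognized optional columns: `patient_id`, `subgroup`, and the QC fields
#' `mphsd_um`, `fp_pct`, `fn_pct`, `fl_pct`, `oct_signal_db`.
#'
#' @param path CSV file path.
#' @return Data frame of visit records.
#' @export
read_cohort <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("eye_id", "t", "structural_value", "functional_value")
  missing_cols <- setdiff(needed, names(rec))
  if (length(missing_cols)) {
    stop_dsf("cohort file lacks columns: ",
             paste(missing_cols, collapse = ", "))
  }
  rec
}
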