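# Builders for in-code fixtures: eyes on exact linear trajectories and small
# randomized cohorts.

linear_series <- function(times, f0 = 100, s0 = 95, rate_f = -2,
                          rate_s = -1.5) {
  data.frame(t = times, f_pct = f0 + rate_f * times,
             s_pct = s0 + rate_s * times)
}

linear_eye <- function(eye_id, times = seq(0, 3, by = 0.5), f0 = 100,
                       s0 = 95, rate_f = -2, rate_s = -1.5,
                       subgroup = "both") {
  structure(list(eye_id = eye_id, patient_id = eye_id, subgroup = subgroup,
                 series = linear_series(times, f0, s0, rate_f, rate_s)),
            class = "eye_series")
}

noiseless_cohort <- function(n_eyes = 10, n_visits = 7) {
  lapply(seq_len(n_eyes), function(i) {
    linear_eye(sprintf("eye%03d", i), times = seq(0, by = 0.5,
                                                  length.out = n_visits),
               f0 = 90 + i, s0 = 85 + i, rate_f = -1 - 0.1 * i,
               rate_s = -0.5 - 0.05 * i)
  })
}

# one reliable RA_MS visit record; override fields to violate rules
visit_record <- function(eye_id = "e1", t = 0, ...) {
  rec <- data.frame(eye_id = eye_id, patient_id = eye_id, t = t,
                    structural_value = 1.2, structural_unit = "mm2",
                    functional_value = 28, functional_unit = "dB_MS",
                    mphsd_um = 30, fp_pct = 10, fn_pct = 10, fl_pct = 10,
                    oct_signal_db = NA_real_, subgroup = "both",
                    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

reliable_eye_records <- function(eye_id, n_visits = 7, gap = 0.5) {
  do.call(rbind, lapply(seq_len(n_visits), function(v) {
    visit_record(eye_id, t = (v - 1) * gap)
  }))
}
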