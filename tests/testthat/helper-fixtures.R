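# Small deterministic corpora built in code.

# One study with explicit per-wave counts/moments.
fixture_study <- function(id, waves, n_baseline = max(waves$n_assessed),
                          mean_age = 12, pct_male = 55, measure_type = 0L,
                          acute_timing = 0L, informant = "child") {
  study_record(study_id = id, n_baseline = n_baseline, mean_age = mean_age,
               pct_male = pct_male, measure_type = measure_type,
               acute_timing = acute_timing, trauma_type = "accidental_injury",
               informant = informant, waves = waves)
}

# k identical studies: x/n cases at each month, optional symptom moments.
homogeneous_corpus <- function(k, months, x, n, sympt_mean = NA,
                               sympt_sd = NA) {
  studies <- lapply(seq_len(k), function(i) {
    waves <- data.frame(nominal_month = months,
                        n_assessed = rep(n, length(months)),
                        n_ptsd = x,
                        sympt_mean = sympt_mean,
                        sympt_sd = sympt_sd)
    fixture_study(sprintf("S%02d", i), waves)
  })
  longimeta:::new_corpus(studies, provenance = "extracted")
}

# Minimal long-format CSV written to a tempfile; returns the path.
write_fixture_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

minimal_row <- function(study_id = "S1", nominal_month = 1,
                        n_assessed = 81, n_ptsd = 20, n_baseline = 81,
                        actual_weeks = NA, sympt_mean = NA, sympt_sd = NA) {
  data.frame(study_id = study_id, n_baseline = n_baseline, mean_age = 12.3,
             pct_male = 55, measure_type = 0, acute_timing = 0,
             trauma_type = "accidental_injury", informant = "child",
             nominal_month = nominal_month, actual_weeks = actual_weeks,
             n_assessed = n_assessed, n_ptsd = n_ptsd,
             sympt_mean = sympt_mean, sympt_sd = sympt_sd,
             stringsAsFactors = FALSE)
}
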