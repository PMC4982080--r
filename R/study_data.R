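#' @importFrom utils read.csv write.csv
NULL

# Nominal assessment windows in weeks since trauma. The 1-month ("acute")
# window is ~1 month +/- 2 weeks; the 3-, 6- and 12-month windows are
# +/- 1 month. Closed intervals; the four windows are disjoint, so
# assignment is deterministic.
.wave_windows <- data.frame(
  nominal_month = c(1L, 3L, 6L, 12L),
  lo_weeks      = c(2,   9,  22,  48),
  hi_weeks      = c(6,  17,  30,  57)
)

.nominal_months <- c(1L, 3L, 6L, 12L)

# Long-CSV schema for study-level corpora, in canonical column order.
.corpus_columns <- c(
  "study_id", "n_baseline", "mean_age", "pct_male", "measure_type",
  "acute_timing", "trauma_type", "informant", "nominal_month",
  "actual_weeks", "n_assessed", "n_ptsd", "sympt_mean", "sympt_sd"
)

#' Map an actual assessment time to its nominal follow-up wave
#'
#' Assessment waves are harmonized to nominal posttrauma months 1, 3, 6 and
#' 12. An actual timing (in weeks since trauma) is assigned to the unique
#' window containing it: 2--6 weeks for 1 month, 9--17 for 3 months,
#' 22--30 for 6 months, 48--57 for 12 months (closed intervals). Timings
#' falling between windows get `NA`: such assessments cannot be harmonized.
#'
#' @param actual_weeks Numeric vector of weeks since trauma (> 0).
#' @return Integer vector of nominal months (1, 3, 6, 12) or `NA`.
#' @examples
#' assign_nominal_wave(c(2, 30, 40))  # 1, 6, NA
#' @export
assign_nominal_wave <- function(actual_weeks) {
  stopifnot(is.numeric(actual_weeks), all(actual_weeks > 0, na.rm = TRUE))
  out <- rep(NA_integer_, length(actual_weeks))
  for (i in seq_len(nrow(.wave_windows))) {
    hit <- !is.na(actual_weeks) &
      actual_weeks >= .wave_windows$lo_weeks[i] &
      actual_weeks <= .wave_windows$hi_weeks[i]
    out[hit] <- .wave_windows$nominal_month[i]
  }
  out
}

#' Construct a single study record
#'
#' A study record couples the study-level moderators used in
#' meta-regression with the per-wave outcome data (PTSD case counts and/or
#' symptom means). `waves` is a data frame with one row per assessment
#' wave, columns `nominal_month`, `actual_weeks`, `n_assessed`, `n_ptsd`,
#' `sympt_mean`, `sympt_sd` (missing columns are filled with `NA`).
#'
#' @param study_id Short unique label.
#' @param n_baseline Total sample at the first PTSD assessment.
#' @param mean_age Mean age of the sample in years.
#' @param pct_male Percentage of boys, 0--100.
#' @param measure_type 0 = self-report questionnaire with cut-off,
#'   1 = diagnostic interview.
#' @param acute_timing 0 = first assessment at < 4 weeks posttrauma,
#'   1 = at 4--6 weeks; `NA` when the study has no acute wave.
#' @param trauma_type Free-text primary trauma type.
#' @param informant `"child"` or `"parent"`; parent-only studies are
#'   accepted but flagged, since parents tend to under-report.
#' @param waves Data frame of wave observations (see Details).
#' @return An object of class `study_record`.
#' @export
study_record <- function(study_id, n_baseline, mean_age = NA_real_,
                         pct_male = NA_real_, measure_type = NA_integer_,
                         acute_timing = NA_integer_,
                         trauma_type = NA_character_, informant = "child",
                         waves) {
  stopifnot(is.data.frame(waves))
  for (col in c("nominal_month", "actual_weeks", "n_assessed", "n_ptsd",
                "sympt_mean", "sympt_sd")) {
    if (is.null(waves[[col]])) waves[[col]] <- NA_real_
  }
  waves <- waves[, c("nominal_month", "actual_weeks", "n_assessed", "n_ptsd",
                     "sympt_mean", "sympt_sd"), drop = FALSE]
  rownames(waves) <- NULL
  structure(
    list(study_id = as.character(study_id),
         n_baseline = as.numeric(n_baseline),
         mean_age = as.numeric(mean_age),
         pct_male = as.numeric(pct_male),
         measure_type = as.integer(measure_type),
         acute_timing = as.integer(acute_timing),
         trauma_type = as.character(trauma_type),
         informant = as.character(informant),
         waves = waves),
    class = "study_record")
}

#' Validate a study record
#'
#' Diagnostic check of all study-level invariants. Returns a character
#' vector of issues (empty when the record is well formed); each issue
#' names the offending field and rule. Records are never silently
#' repaired -- in particular, out-of-order waves are reported, not
#' reordered.
#'
#' @param record A [study_record()].
#' @return Character vector of issues; `character(0)` if valid.
#' @export
validate_study <- function(record) {
  stopifnot(inherits(record, "study_record"))
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)
  w <- record$waves

  if (nrow(w) == 0) add("waves: must be non-empty")
  if (!is.na(record$pct_male) &&
      (record$pct_male < 0 || record$pct_male > 100))
    add(sprintf("pct_male: %s outside [0, 100]", record$pct_male))
  if (!is.na(record$measure_type) && !record$measure_type %in% c(0L, 1L))
    add("measure_type: must be 0 (self-report cut-off) or 1 (interview)")
  if (!is.na(record$acute_timing) && !record$acute_timing %in% c(0L, 1L))
    add("acute_timing: must be 0 (<4 weeks) or 1 (4-6 weeks)")
  if (!record$informant %in% c("child", "parent"))
    add("informant: must be 'child' or 'parent'")
  if (is.na(record$n_baseline) || record$n_baseline < 1)
    add("n_baseline: must be a positive count")

  if (nrow(w) > 0) {
    if (any(!w$nominal_month %in% .nominal_months))
      add("waves: nominal_month must be one of 1, 3, 6, 12")
    if (anyDuplicated(w$nominal_month))
      add("waves: duplicate nominal_month")
    if (is.unsorted(w$nominal_month, strictly = TRUE))
      add("waves: nominal months must be in ascending order")
    if (!is.na(record$n_baseline) &&
        any(w$n_assessed > record$n_baseline, na.rm = TRUE))
      add("n_baseline: smaller than a wave's n_assessed")
    for (i in seq_len(nrow(w))) {
      m <- w$nominal_month[i]
      if (!is.na(w$n_ptsd[i]) && is.na(w$n_assessed[i]))
        add(sprintf("wave %s: n_ptsd present without n_assessed", m))
      if (!is.na(w$n_ptsd[i]) && !is.na(w$n_assessed[i]) &&
          (w$n_ptsd[i] < 0 || w$n_ptsd[i] > w$n_assessed[i]))
        add(sprintf("wave %s: n_ptsd (%s) outside [0, n_assessed = %s]",
                    m, w$n_ptsd[i], w$n_assessed[i]))
      has_sympt <- !is.na(w$sympt_mean[i]) && !is.na(w$sympt_sd[i])
      if (is.na(w$n_ptsd[i]) && !has_sympt)
        add(sprintf("wave %s: needs n_ptsd or (sympt_mean, sympt_sd)", m))
      if (!is.na(w$sympt_sd[i]) && w$sympt_sd[i] < 0)
        add(sprintf("wave %s: sympt_sd must be >= 0", m))
      if (!is.na(w$actual_weeks[i]) && m %in% .nominal_months) {
        assigned <- assign_nominal_wave(w$actual_weeks[i])
        if (is.na(assigned) || assigned != m)
          add(sprintf(
            "wave %s: actual_weeks = %s outside the nominal window",
            m, w$actual_weeks[i]))
      }
    }
  }
  issues
}

new_corpus <- function(studies, provenance = c("extracted", "synthetic"),
                       seed = NULL) {
  provenance <- match.arg(provenance)
  ids <- vapply(studies, function(s) s$study_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate study_id: ", paste(unique(ids[duplicated(ids)]),
                                       collapse = ", "))
  names(studies) <- ids
  structure(list(studies = studies, provenance = provenance, seed = seed),
            class = "ptsd_corpus")
}

#' @export
print.ptsd_corpus <- function(x, ...) {
  k <- length(x$studies)
  nw <- vapply(x$studies, function(s) nrow(s$waves), integer(1))
  cat(sprintf("<ptsd_corpus> %d studies (%s), %d study-waves\n",
              k, x$provenance, sum(nw)))
  invisible(x)
}

#' @export
length.ptsd_corpus <- function(x) length(x$studies)

#' Flatten a corpus to the long one-row-per-study-wave table
#'
#' @param x A `ptsd_corpus`.
#' @param row.names,optional,... Ignored; present for method compatibility.
#' @return Data frame in the documented long CSV schema.
#' @export
as.data.frame.ptsd_corpus <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  rows <- lapply(x$studies, function(s) {
    cbind(
      data.frame(study_id = s$study_id, n_baseline = s$n_baseline,
                 mean_age = s$mean_age, pct_male = s$pct_male,
                 measure_type = s$measure_type,
                 acute_timing = s$acute_timing,
                 trauma_type = s$trauma_type, informant = s$informant,
                 stringsAsFactors = FALSE),
      s$waves)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, .corpus_columns]
}

#' Load a study-level corpus from a long-format CSV
#'
#' Reads the documented long schema (one row per study x assessment wave;
#' UTF-8, comma-separated, `.` decimal, empty cell = missing), merges rows
#' sharing a `study_id` into one study record with waves ordered by
#' nominal month, and validates every record. A missing `n_assessed` at a
#' follow-up wave defaults to `n_baseline` with a warning (the fallback
#' used when attrition is unreported). Parent-report studies are accepted
#' with a warning flag.
#'
#' @param path Path to the CSV file.
#' @param provenance `"extracted"` (default) or `"synthetic"`.
#' @return A validated `ptsd_corpus`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(study_id = "S1", n_baseline = 81, mean_age = 12.3,
#'                      pct_male = 55, measure_type = 0, acute_timing = 0,
#'                      trauma_type = "accidental_injury", informant = "child",
#'                      nominal_month = 1, actual_weeks = 2, n_assessed = 81,
#'                      n_ptsd = 20, sympt_mean = NA, sympt_sd = NA),
#'           f, row.names = FALSE)
#' load_corpus(f)
#' @export
load_corpus <- function(path, provenance = "extracted") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.corpus_columns, names(raw))
  if (length(missing_cols) > 0)
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  raw <- raw[, .corpus_columns]
  for (col in c("n_baseline", "mean_age", "pct_male", "actual_weeks",
                "n_assessed", "n_ptsd", "sympt_mean", "sympt_sd"))
    raw[[col]] <- as.numeric(raw[[col]])
  for (col in c("measure_type", "acute_timing", "nominal_month"))
    raw[[col]] <- as.integer(raw[[col]])

  key <- paste(raw$study_id, raw$nominal_month)
  if (anyDuplicated(key))
    stop("validation error: duplicate (study_id, nominal_month): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))

  defaulted <- character(0)
  studies <- lapply(split(raw, raw$study_id), function(d) {
    d <- d[order(d$nominal_month), , drop = FALSE]
    meta_cols <- c("n_baseline", "mean_age", "pct_male", "measure_type",
                   "acute_timing", "trauma_type", "informant")
    for (col in meta_cols) {
      u <- unique(d[[col]][!is.na(d[[col]])])
      if (length(u) > 1)
        warning(sprintf("study %s: inconsistent %s across rows; using first",
                        d$study_id[1], col), call. = FALSE)
    }
    fill <- is.na(d$n_assessed)
    if (any(fill)) {
      d$n_assessed[fill] <- d$n_baseline[1]
      defaulted <<- c(defaulted, d$study_id[1])
    }
    study_record(
      study_id = d$study_id[1], n_baseline = d$n_baseline[1],
      mean_age = d$mean_age[1], pct_male = d$pct_male[1],
      measure_type = d$measure_type[1], acute_timing = d$acute_timing[1],
      trauma_type = d$trauma_type[1], informant = d$informant[1],
      waves = d[, c("nominal_month", "actual_weeks", "n_assessed",
                    "n_ptsd", "sympt_mean", "sympt_sd")])
  })
  if (length(defaulted) > 0)
    warning("n_assessed missing; defaulted to n_baseline for study(ies): ",
            paste(unique(defaulted), collapse = ", "), call. = FALSE)

  corpus <- new_corpus(unname(studies), provenance = provenance)
  for (s in corpus$studies) {
    issues <- validate_study(s)
    if (length(issues) > 0)
      stop("validation error in study ", s$study_id, ": ",
           paste(issues, collapse = "; "))
  }
  parent_only <- vapply(corpus$studies,
                        function(s) identical(s$informant, "parent"),
                        logical(1))
  if (any(parent_only))
    warning("parent-report study(ies) flagged: ",
            paste(names(corpus$studies)[parent_only], collapse = ", "),
            call. = FALSE)
  corpus
}

#' Write a corpus back to the long CSV schema
#'
#' Inverse of [load_corpus()]: numeric cells are written with 15
#' significant digits, so `load_corpus(write_corpus(x))` reproduces `x`
#' field-for-field to that precision.
#'
#' @param corpus A `ptsd_corpus`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "ptsd_corpus"))
  write_results(as.data.frame(corpus), path)
}

#' Write a result table as CSV with a deterministic column order
#'
#' @param results A non-empty data frame (or an object with an
#'   `as.data.frame` method, e.g. a `pooled_result`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  results <- as.data.frame(results)
  if (nrow(results) == 0) stop("results table is empty; nothing to write")
  num <- vapply(results, is.numeric, logical(1))
  results[num] <- lapply(results[num], function(x) {
    ifelse(is.na(x), NA, formatC(x, digits = 15, format = "g"))
  })
  ok <- tryCatch({
    write.csv(results, path, row.names = FALSE, quote = TRUE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Metadata of the 28 source cohort studies
#'
#' Returns the bundled study-level metadata table (sample sizes, ages,
#' percent male, trauma types, assessment timings and instruments) for the
#' 28 longitudinal cohorts of trauma-exposed children the analysis design
#' is calibrated to. Outcome counts per wave are not included; those are
#' user-supplied or simulated.
#'
#' @return Data frame with one row per study.
#' @examples
#' head(table1_metadata())
#' @export
table1_metadata <- function() {
  path <- system.file("extdata", "table1_metadata.csv", package = "longimeta")
  read.csv(path, stringsAsFactors = FALSE)
}
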