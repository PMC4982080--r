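# Orchestration: the full analysis suite over one corpus, plus the
# attrition / correlation sensitivity suite. All analysis stages are
# pure; randomness lives only in the simulator.

.default_frames <- list(c(1L, 3L), c(3L, 6L), c(1L, 6L), c(3L, 12L))

collect_flag_log <- function(effects, analysis) {
  flagged <- effects[nzchar(effects$flags), , drop = FALSE]
  if (nrow(flagged) == 0) return(character(0))
  sprintf("%s | study %s | %s", analysis, flagged$study_id, flagged$flags)
}

#' Run the full longitudinal meta-analysis over a corpus
#'
#' Executes every configured analysis: pooled point prevalence at each
#' month, pooled prevalence reduction for each frame under each attrition
#' variant, and pooled standardized mean change for each frame under each
#' assumed correlation; then moderator screens and funnel diagnostics for
#' the primary analyses. Analyses with fewer than `min_k` eligible
#' studies (or none) are reported in the analysis skip ledger rather than
#' failing the run. Every continuity correction, clamp and attrition
#' imputation is logged. The run is deterministic given the corpus.
#'
#' @param corpus A `ptsd_corpus`.
#' @param months Nominal months for point-prevalence analyses.
#' @param frames List of month pairs for change analyses.
#' @param variants Attrition variants for reduction analyses.
#' @param r_values Assumed pre-post correlations for smc analyses.
#' @param min_k Minimum studies per analysis (default 3).
#' @param run_moderators Whether to run the moderator screens.
#' @param out_dir Optional directory; if given, result CSVs, a run log
#'   and a manifest are written there.
#' @return An object of class `analysis_bundle`: data frames `pooled`,
#'   `forest`, `moderators`, `moderator_skips`, `funnel`,
#'   `analysis_skips`, `study_skips`, and a character `log`.
#' @export
run_full_analysis <- function(corpus,
                              months = c(1L, 3L, 6L, 12L),
                              frames = .default_frames,
                              variants = c("mcar", "all_dropouts_ptsd",
                                           "no_dropouts_ptsd"),
                              r_values = c(0.2, 0.4, 0.6, 0.8),
                              min_k = 3, run_moderators = TRUE,
                              out_dir = NULL) {
  stopifnot(inherits(corpus, "ptsd_corpus"))
  pooled <- list(); forest <- list(); mods <- list(); mod_skips <- list()
  funnel <- list(); a_skips <- list(); s_skips <- list()
  log_lines <- character(0)

  skip_analysis <- function(analysis, reason)
    a_skips[[length(a_skips) + 1]] <<- data.frame(
      analysis = analysis, reason = reason, stringsAsFactors = FALSE)

  run_one <- function(analysis, build, pool) {
    es <- tryCatch(build(), error = function(e) conditionMessage(e))
    if (is.character(es)) { skip_analysis(analysis, es); return(NULL) }
    if (nrow(es$effects) < min_k) {
      skip_analysis(analysis, sprintf("k = %d below min_k = %d",
                                      nrow(es$effects), min_k))
      return(NULL)
    }
    res <- pool_effect_set(es, analysis)
    pooled[[length(pooled) + 1]] <<- as.data.frame(res)
    fd <- forest_data(res)
    fd$analysis <- analysis
    forest[[length(forest) + 1]] <<- fd
    if (nrow(es$skipped) > 0) {
      sk <- es$skipped
      sk$analysis <- analysis
      s_skips[[length(s_skips) + 1]] <<- sk
    }
    log_lines <<- c(log_lines, collect_flag_log(es$effects, analysis))
    es
  }

  screen_one <- function(analysis, type, month = 1, frame = c(1, 6)) {
    scr <- tryCatch(
      moderator_screen(corpus, type, month = month, frame = frame),
      error = function(e) NULL)
    if (is.null(scr)) return(invisible(NULL))
    for (m in scr$results)
      mods[[length(mods) + 1]] <<- as.data.frame(m)
    if (nrow(scr$skipped) > 0) {
      sk <- scr$skipped
      sk$analysis <- analysis
      mod_skips[[length(mod_skips) + 1]] <<- sk
    }
  }

  funnel_one <- function(analysis, es) {
    if (is.null(es) || nrow(es$effects) < 3) return(invisible(NULL))
    fd <- funnel_diagnostics(es, label = analysis)
    funnel[[length(funnel) + 1]] <<- data.frame(
      analysis = analysis, k = nrow(fd$points),
      egger_intercept = fd$egger_intercept, egger_se = fd$egger_se,
      egger_p = fd$egger_p, stringsAsFactors = FALSE)
  }

  for (m in months) {
    analysis <- sprintf("prevalence_month%d", m)
    es <- run_one(analysis,
                  function() build_effects_for_frame(corpus, m,
                                                     "logit_prevalence"),
                  NULL)
    funnel_one(analysis, es)
    if (run_moderators && !is.null(es))
      screen_one(analysis, "point_prevalence", month = m)
  }
  for (fr in frames) {
    for (v in variants) {
      analysis <- sprintf("reduction_%s_%s", frame_label(fr), v)
      es <- run_one(analysis,
                    function() build_effects_for_frame(
                      corpus, fr, "logit_reduction", variant = v),
                    NULL)
      if (v == "mcar") {
        funnel_one(analysis, es)
        if (run_moderators && !is.null(es))
          screen_one(analysis, "reduction", frame = fr)
      }
    }
    for (r in r_values) {
      analysis <- sprintf("smc_%s_r%s", frame_label(fr), r)
      es <- run_one(analysis,
                    function() build_effects_for_frame(
                      corpus, fr, "smc", r_assumed = r),
                    NULL)
      if (r == r_values[1]) {
        funnel_one(analysis, es)
        if (run_moderators && !is.null(es))
          screen_one(analysis, "smc", frame = fr)
      }
    }
  }

  bind <- function(lst, empty) {
    if (length(lst) > 0) do.call(rbind, lst) else empty
  }
  bundle <- structure(
    list(
      pooled = bind(pooled, NULL),
      forest = bind(forest, NULL),
      moderators = bind(mods, NULL),
      moderator_skips = bind(mod_skips, NULL),
      funnel = bind(funnel, NULL),
      analysis_skips = bind(a_skips,
                            data.frame(analysis = character(0),
                                       reason = character(0))),
      study_skips = bind(s_skips,
                         data.frame(study_id = character(0),
                                    reason = character(0),
                                    analysis = character(0))),
      log = log_lines),
    class = "analysis_bundle")

  if (!is.null(out_dir)) write_bundle(bundle, corpus, out_dir)
  bundle
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat(sprintf(
    "<analysis_bundle> %d pooled analyses, %d skipped, %d log line(s)\n",
    if (is.null(x$pooled)) 0L else nrow(x$pooled),
    nrow(x$analysis_skips), length(x$log)))
  invisible(x)
}

# Polynomial rolling hash over the serialized config; a content
# fingerprint for manifests (not cryptographic).
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, ascii = TRUE))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_bundle <- function(bundle, corpus, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("pooled", "forest", "moderators", "funnel",
               "analysis_skips", "study_skips")) {
    tab <- bundle[[nm]]
    if (!is.null(tab) && nrow(tab) > 0)
      write_results(tab, file.path(out_dir, paste0(nm, ".csv")))
  }
  writeLines(bundle$log, file.path(out_dir, "run_log.txt"))
  manifest <- list(
    package = "longimeta",
    version = as.character(utils::packageVersion("longimeta")),
    n_studies = length(corpus), provenance = corpus$provenance,
    seed = corpus$seed,
    config_hash = config_hash(list(corpus = as.data.frame(corpus))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Attrition and correlation sensitivity suite
#'
#' Side-by-side pooled estimates for each reduction frame across the
#' three attrition variants, and for each smc frame across the assumed
#' correlation grid, with a qualitative robustness verdict per frame: do
#' all variants agree on whether the CI excludes "no change"? For the
#' reduction scale "no change" is the 1\% floor the logit transform
#' requires; for smc it is d = 0.
#'
#' @param corpus A `ptsd_corpus`.
#' @param frames List of month pairs.
#' @param variants Attrition variants.
#' @param r_values Assumed correlations.
#' @param min_k Minimum studies per analysis.
#' @return List of data frames `reduction` and `smc` (either may be
#'   `NULL` if no frame had enough studies); each row carries the pooled
#'   back-transformed estimate, CI, a `significant` flag and a `robust`
#'   verdict shared by the frame.
#' @export
sensitivity_suite <- function(corpus, frames = .default_frames,
                              variants = c("mcar", "all_dropouts_ptsd",
                                           "no_dropouts_ptsd"),
                              r_values = c(0.2, 0.4, 0.6, 0.8),
                              min_k = 3) {
  red <- list(); smc <- list()
  for (fr in frames) {
    rows <- lapply(variants, function(v) {
      res <- tryCatch(pool_reduction(corpus, fr, variant = v),
                      error = function(e) NULL)
      if (is.null(res) || res$k < min_k) return(NULL)
      data.frame(frame = frame_label(fr), variant = v, k = res$k,
                 estimate_bt = res$estimate_bt, ci_lo_bt = res$ci_lo_bt,
                 ci_hi_bt = res$ci_hi_bt,
                 significant = res$ci_lo_bt > 0.01,
                 stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    if (!is.null(rows) && nrow(rows) == length(variants)) {
      rows$robust <- length(unique(rows$significant)) == 1
      red[[length(red) + 1]] <- rows
    }
    rows <- lapply(r_values, function(r) {
      res <- tryCatch(pool_symptom_change(corpus, fr, r_assumed = r),
                      error = function(e) NULL)
      if (is.null(res) || res$k < min_k) return(NULL)
      data.frame(frame = frame_label(fr), r_assumed = r, k = res$k,
                 estimate_bt = res$estimate_bt, ci_lo_bt = res$ci_lo_bt,
                 ci_hi_bt = res$ci_hi_bt,
                 significant = res$ci_lo_bt > 0,
                 stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    if (!is.null(rows) && nrow(rows) == length(r_values)) {
      rows$robust <- length(unique(rows$significant)) == 1
      smc[[length(smc) + 1]] <- rows
    }
  }
  list(reduction = if (length(red) > 0) do.call(rbind, red) else NULL,
       smc = if (length(smc) > 0) do.call(rbind, smc) else NULL)
}
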