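# Per-study effect sizes on the three working scales:
#   logit_prevalence  logit of a point prevalence x/n
#   logit_reduction   logit of the relative prevalence reduction
#                     R = 1 - (cases at T2 / cases at T1)
#   smc               standardized mean symptom change, pooled-SD denominator

.variants <- c("mcar", "all_dropouts_ptsd", "no_dropouts_ptsd")

effect_row <- function(study_id, scale, frame, estimate, se, n_effective,
                       variant = "not_applicable", r_assumed = NA_real_,
                       flags = character(0)) {
  data.frame(study_id = study_id, scale = scale, frame = frame_label(frame),
             variant = variant, r_assumed = r_assumed, estimate = estimate,
             se = se, n_effective = n_effective,
             flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)
}

#' Logit-transformed point prevalence for one study wave
#'
#' The proportion of assessed children meeting PTSD criteria, expressed as
#' a log-odds with the binomial delta-method standard error
#' \eqn{\sqrt{1/x + 1/(n-x)}}. Boundary counts (`x = 0` or `x = n`) get
#' the standard 0.5 continuity correction applied to both cells
#' (`x' = x + 0.5`, `n' = n + 1`), recorded in `flags`.
#'
#' @param x Number of PTSD cases (0 <= x <= n).
#' @param n Number of children assessed (>= 1).
#' @param month Nominal posttrauma month, for labelling.
#' @param study_id Study label.
#' @return One-row effect-size data frame (columns `study_id`, `scale`,
#'   `frame`, `variant`, `r_assumed`, `estimate`, `se`, `n_effective`,
#'   `flags`).
#' @examples
#' logit_prevalence_effect(21, 100)  # estimate log(21/79), se ~0.246
#' @export
logit_prevalence_effect <- function(x, n, month = NA_integer_,
                                    study_id = "study") {
  if (length(n) != 1 || is.na(n) || n < 1) stop("n must be >= 1")
  if (is.na(x) || x < 0 || x > n) stop("x must satisfy 0 <= x <= n")
  flags <- character(0)
  if (x == 0 || x == n) {
    x <- x + 0.5
    n <- n + 1
    flags <- "continuity_applied"
  }
  effect_row(study_id, "logit_prevalence", month,
             estimate = log(x / (n - x)),
             se = sqrt(1 / x + 1 / (n - x)),
             n_effective = n, flags = flags)
}

#' Impute total PTSD cases at follow-up under an attrition assumption
#'
#' Between two assessment waves some of the `N` children assessed at T1
#' are lost to follow-up; only `m` completers are reassessed, `c` of whom
#' still meet criteria. The total T2 case count is imputed under one of
#' three assumptions about the `N - m` dropouts:
#' \describe{
#'   \item{`mcar`}{dropouts carry the T1 PTSD proportion `n1/N`
#'     (primary analysis): `c + (N - m) * n1/N`, possibly fractional.}
#'   \item{`all_dropouts_ptsd`}{every dropout is a case: `c + (N - m)`.}
#'   \item{`no_dropouts_ptsd`}{no dropout is a case: `c`.}
#' }
#' Fractional totals are kept unrounded.
#'
#' @param n1 PTSD cases at T1.
#' @param c_obs Observed cases at T2 among completers.
#' @param m Completers reassessed at T2 (>= 1).
#' @param N Children assessed at T1.
#' @param variant One of `"mcar"`, `"all_dropouts_ptsd"`,
#'   `"no_dropouts_ptsd"`.
#' @return Imputed total T2 case count (numeric, possibly fractional).
#' @examples
#' impute_t2_cases(20, 8, 80, 100, "mcar")  # 12
#' @export
impute_t2_cases <- function(n1, c_obs, m, N, variant = .variants) {
  variant <- match.arg(variant)
  if (is.na(m) || m < 1) stop("m = 0: no follow-up data to impute from")
  if (c_obs < 0 || c_obs > m) stop("need 0 <= c_obs <= m")
  if (m > N) stop("completers m cannot exceed the T1 sample N")
  if (n1 < 0 || n1 > N) stop("need 0 <= n1 <= N")
  switch(variant,
         mcar = c_obs + (N - m) * (n1 / N),
         all_dropouts_ptsd = c_obs + (N - m),
         no_dropouts_ptsd = c_obs)
}

#' Relative prevalence-reduction effect size between two waves
#'
#' The fraction of T1 cases who lost the PTSD diagnosis by T2,
#' `R = 1 - t2_cases/n1` (in the source analyses,
#' 100\% minus the T2/T1 case ratio), logit-transformed for pooling. When
#' the case count did not change (`R = 0`), 0.01 (i.e. 1\%) is substituted
#' to allow the logit transformation; the same clamp extends to increases
#' (`R < 0`) and to complete recovery (`R = 1`, clamped at 0.99). Because
#' the analysis concerns only the subset with PTSD at T1, the standard
#' error uses the number of cases at that time point rather than the whole
#' sample: `se = sqrt(1/(n1*R) + 1/(n1*(1-R)))`.
#'
#' @param n1 PTSD cases at T1 (>= 1; studies with none are excluded from
#'   this analysis).
#' @param t2_cases Total (possibly imputed, possibly fractional) cases at
#'   T2; see [impute_t2_cases()].
#' @param frame Length-2 vector of nominal months, e.g. `c(1, 6)`.
#' @param variant Attrition variant used to produce `t2_cases`.
#' @param study_id Study label.
#' @param extra_flags Additional flags to record (e.g.
#'   `"attrition_imputed"`).
#' @return One-row effect-size data frame on the `logit_reduction` scale.
#' @examples
#' prevalence_reduction_effect(20, 10, c(1, 6))  # R = 0.5, estimate 0
#' @export
prevalence_reduction_effect <- function(n1, t2_cases, frame = c(1L, 6L),
                                        variant = "mcar",
                                        study_id = "study",
                                        extra_flags = character(0)) {
  if (is.na(n1) || n1 < 1)
    stop("n1 = 0: no initial cases; study excluded from this analysis")
  if (is.na(t2_cases) || t2_cases < 0) stop("t2_cases must be >= 0")
  R <- 1 - t2_cases / n1
  flags <- extra_flags
  if (R <= 0) {
    R <- 0.01
    flags <- c(flags, "continuity_applied", "clamped")
  } else if (R >= 1) {
    R <- 0.99
    flags <- c(flags, "clamped")
  }
  effect_row(study_id, "logit_reduction", frame, variant = variant,
             estimate = logit(R),
             se = sqrt(1 / (n1 * R) + 1 / (n1 * (1 - R))),
             n_effective = n1, flags = flags)
}

#' Standardized mean symptom change between two waves
#'
#' Change in a cohort's mean PTSD symptom score divided by the pooled
#' standard deviation, `d = (m1 - m2) / sqrt((sd1^2 + sd2^2)/2)`; positive
#' `d` means symptom decline. Because the two means come from the same
#' children, the sampling variance depends on the (rarely reported)
#' pre-post correlation `r`: `var = 2(1-r)/n + d^2/(2n)`. The analysis is
#' therefore run over a grid of assumed correlations (0.2, 0.4, 0.6, 0.8);
#' the point estimate does not depend on `r`, only the variance does.
#'
#' @param m1,sd1 Mean and SD at the earlier wave.
#' @param m2,sd2 Mean and SD at the later wave (`sd1`, `sd2` > 0).
#' @param n Number of children contributing to both waves (>= 2).
#' @param r_assumed Assumed pre-post correlation in (0, 1).
#' @param frame Length-2 vector of nominal months.
#' @param study_id Study label.
#' @return One-row effect-size data frame on the `smc` scale.
#' @examples
#' symptom_change_effect(30, 10, 25, 10, n = 50, r_assumed = 0.6)
#' @export
symptom_change_effect <- function(m1, sd1, m2, sd2, n, r_assumed = 0.6,
                                  frame = c(1L, 6L), study_id = "study") {
  if (is.na(sd1) || is.na(sd2) || sd1 <= 0 || sd2 <= 0)
    stop("standard deviations must be > 0")
  if (is.na(n) || n < 2) stop("n must be >= 2")
  if (is.na(r_assumed) || r_assumed <= 0 || r_assumed >= 1)
    stop("r_assumed must be in (0, 1)")
  d <- (m1 - m2) / sqrt((sd1^2 + sd2^2) / 2)
  v <- 2 * (1 - r_assumed) / n + d^2 / (2 * n)
  effect_row(study_id, "smc", frame, estimate = d, se = sqrt(v),
             n_effective = n, r_assumed = r_assumed)
}

#' Build per-study effect sizes for one analysis frame
#'
#' Walks a corpus and constructs one effect size per eligible study for
#' the requested analysis: a single nominal month for point prevalence, or
#' a pair of months for prevalence reduction / symptom change. Studies
#' lacking the required waves or fields are skipped, with the reason
#' recorded in the skip report. For prevalence reduction, attrition
#' between the two waves is handled by [impute_t2_cases()] under the
#' requested `variant`, and the `attrition_imputed` flag marks studies
#' where completers at T2 were fewer than the T1 sample.
#'
#' @param corpus A `ptsd_corpus`.
#' @param frame Single nominal month (point prevalence) or ascending pair.
#' @param scale `"logit_prevalence"`, `"logit_reduction"` or `"smc"`.
#' @param variant Attrition variant (`logit_reduction` only).
#' @param r_assumed Assumed pre-post correlation (`smc` only).
#' @return An object of class `effect_set`: list with `effects` (data
#'   frame of effect sizes), `skipped` (data frame `study_id`, `reason`),
#'   `frame` and `scale`.
#' @export
build_effects_for_frame <- function(corpus, frame,
                                    scale = c("logit_prevalence",
                                              "logit_reduction", "smc"),
                                    variant = "mcar", r_assumed = 0.6) {
  stopifnot(inherits(corpus, "ptsd_corpus"))
  scale <- match.arg(scale)
  frame <- as.integer(frame)
  if (!all(frame %in% .nominal_months))
    stop("frame months must be among 1, 3, 6, 12")
  if (scale == "logit_prevalence") {
    if (length(frame) != 1) stop("point prevalence takes a single month")
  } else {
    if (length(frame) != 2 || frame[1] >= frame[2])
      stop("change analyses take an ascending pair of months")
  }

  effects <- list()
  skipped <- list()
  skip <- function(id, reason)
    skipped[[length(skipped) + 1]] <<- data.frame(
      study_id = id, reason = reason, stringsAsFactors = FALSE)

  for (s in corpus$studies) {
    w <- s$waves
    get_wave <- function(m) w[w$nominal_month == m, , drop = FALSE]

    if (scale == "logit_prevalence") {
      w1 <- get_wave(frame)
      if (nrow(w1) == 0) { skip(s$study_id, sprintf("missing wave %d", frame)); next }
      if (is.na(w1$n_ptsd)) { skip(s$study_id, sprintf("missing n_ptsd at wave %d", frame)); next }
      effects[[length(effects) + 1]] <-
        logit_prevalence_effect(w1$n_ptsd, w1$n_assessed, month = frame,
                                study_id = s$study_id)
      next
    }

    w1 <- get_wave(frame[1]); w2 <- get_wave(frame[2])
    if (nrow(w1) == 0) { skip(s$study_id, sprintf("missing wave %d", frame[1])); next }
    if (nrow(w2) == 0) { skip(s$study_id, sprintf("missing wave %d", frame[2])); next }

    if (scale == "logit_reduction") {
      if (is.na(w1$n_ptsd)) { skip(s$study_id, sprintf("missing n_ptsd at wave %d", frame[1])); next }
      if (is.na(w2$n_ptsd)) { skip(s$study_id, sprintf("missing n_ptsd at wave %d", frame[2])); next }
      if (w1$n_ptsd == 0) { skip(s$study_id, sprintf("no PTSD cases at wave %d", frame[1])); next }
      N <- w1$n_assessed
      m <- min(w2$n_assessed, N)
      flags <- if (m < N) "attrition_imputed" else character(0)
      t2 <- impute_t2_cases(w1$n_ptsd, min(w2$n_ptsd, m), m, N,
                            variant = variant)
      effects[[length(effects) + 1]] <-
        prevalence_reduction_effect(w1$n_ptsd, t2, frame = frame,
                                    variant = variant,
                                    study_id = s$study_id,
                                    extra_flags = flags)
      next
    }

    # smc
    ok1 <- !is.na(w1$sympt_mean) && !is.na(w1$sympt_sd) && w1$sympt_sd > 0
    ok2 <- !is.na(w2$sympt_mean) && !is.na(w2$sympt_sd) && w2$sympt_sd > 0
    if (!ok1) { skip(s$study_id, sprintf("missing symptom scores at wave %d", frame[1])); next }
    if (!ok2) { skip(s$study_id, sprintf("missing symptom scores at wave %d", frame[2])); next }
    n <- min(w1$n_assessed, w2$n_assessed)
    if (is.na(n) || n < 2) { skip(s$study_id, "fewer than 2 children assessed at both waves"); next }
    effects[[length(effects) + 1]] <-
      symptom_change_effect(w1$sympt_mean, w1$sympt_sd, w2$sympt_mean,
                            w2$sympt_sd, n = n, r_assumed = r_assumed,
                            frame = frame, study_id = s$study_id)
  }

  if (length(effects) == 0)
    stop(sprintf("no eligible studies for %s at frame %s", scale,
                 frame_label(frame)))
  structure(
    list(effects = do.call(rbind, effects),
         skipped = if (length(skipped) > 0) do.call(rbind, skipped)
                   else data.frame(study_id = character(0),
                                   reason = character(0),
                                   stringsAsFactors = FALSE),
         frame = frame, scale = scale),
    class = "effect_set")
}

#' @export
print.effect_set <- function(x, ...) {
  cat(sprintf("<effect_set> %s, frame %s: %d effect(s), %d skipped\n",
              x$scale, frame_label(x$frame), nrow(x$effects),
              nrow(x$skipped)))
  invisible(x)
}
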