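# Child-level multi-study simulator with known truth. Studies are
# simulated at the level of individual children so that monotone
# diagnosis loss, delayed onset, attrition and the pre-post symptom
# correlation are all exercised mechanistically, the way the analysis
# assumes they arise.

.canonical_months <- c(1L, 3L, 6L, 12L)
.interval_names <- c("m1_m3", "m3_m6", "m6_m12")

#' Generating truth for a synthetic multi-study corpus
#'
#' Defines the statistical structure the analysis assumes, with every
#' parameter recoverable by the pipeline. Defaults emulate the source
#' corpus of 28 longitudinal cohorts of trauma-exposed children:
#' \itemize{
#'   \item `k = 18` studies of 24--548 children;
#'   \item acute (1-month) prevalence 21\% on average, with between-study
#'     SD `tau = 0.6` on the logit scale (substantial heterogeneity,
#'     expected I2 above 85\%);
#'   \item net relative prevalence reductions per consecutive interval
#'     calibrated so that 17\% of initial cases recover between months
#'     1 and 3 and 53\% between months 1 and 6;
#'   \item delayed onset (a non-case newly meeting criteria at a later
#'     wave) with probability 0.02 per transition;
#'   \item symptom scores bivariate normal per child (mean 30, SD 12 in
#'     arbitrary instrument units; standardization absorbs the scale)
#'     with exchangeable within-child correlation `r_true = 0.6`, wave
#'     means declining so that d = 0.44 between months 1 and 6;
#'   \item 15\% attrition per follow-up wave, missing completely at
#'     random unless `dropout_informative`.
#' }
#'
#' `true_reduction` is the *net* expected relative reduction in case
#' counts per consecutive interval; child-level recovery probabilities
#' are calibrated per study so the net reduction holds exactly in
#' expectation despite delayed-onset inflow. Net reductions compose
#' multiplicatively across intervals (see [implied_reduction()]).
#'
#' @param k Number of studies.
#' @param n_range Integer range of study sample sizes.
#' @param months Nominal assessment months each study observes.
#' @param mu_logit True mean logit prevalence at month 1.
#' @param tau Between-study SD of month-1 logit prevalence.
#' @param true_reduction Named vector of net reductions for `m1_m3`,
#'   `m3_m6`, `m6_m12`, each in (0, 1).
#' @param tau_reduction Between-study SD of the logit net reduction
#'   (a study-level fast/slow-recovery effect shared across intervals).
#' @param delayed_onset_prob Probability a non-case becomes a case at the
#'   next wave.
#' @param r_true Within-child correlation of symptom scores across waves.
#' @param sympt_means Named vector of true symptom means per month.
#' @param sympt_sd True symptom SD (common to waves).
#' @param dropout_rate Per-follow-up-wave dropout probability in [0, 1).
#' @param dropout_informative If `TRUE`, cases are about twice as likely
#'   to drop out as non-cases (violates the MCAR imputation assumption).
#' @param moderator_effects Named numeric vector of slopes added to the
#'   study's logit month-1 prevalence per centered moderator unit; names
#'   among `mean_age`, `pct_male`, `measure_type`, `acute_timing`.
#' @param seed Master seed; per-study substreams are derived from it.
#' @return An object of class `sim_truth`.
#' @examples
#' truth <- sim_truth(k = 4, seed = 1)
#' implied_reduction(truth, c(1, 6))  # 0.53
#' @export
sim_truth <- function(k = 18, n_range = c(24L, 548L),
                      months = c(1L, 3L, 6L, 12L),
                      mu_logit = logit(0.21), tau = 0.6,
                      true_reduction = c(m1_m3 = 0.17,
                                         m3_m6 = 1 - (1 - 0.53) / (1 - 0.17),
                                         m6_m12 = 0.08),
                      tau_reduction = 0.5, delayed_onset_prob = 0.02,
                      r_true = 0.6,
                      sympt_means = c(`1` = 30, `3` = 27.6, `6` = 24.72,
                                      `12` = 23.04),
                      sympt_sd = 12, dropout_rate = 0.15,
                      dropout_informative = FALSE,
                      moderator_effects = numeric(0), seed = 1L) {
  if (k < 1) stop("k must be >= 1")
  stopifnot(length(n_range) == 2, n_range[1] >= 2,
            n_range[1] <= n_range[2])
  months <- sort(as.integer(months))
  if (!all(months %in% .canonical_months))
    stop("months must be among 1, 3, 6, 12")
  if (length(months) < 1) stop("at least one assessment month required")
  p1 <- expit(mu_logit)
  if (!(p1 > 0 && p1 < 1)) stop("mu_logit implies a degenerate prevalence")
  if (tau < 0 || tau_reduction < 0) stop("tau parameters must be >= 0")
  if (!all(.interval_names %in% names(true_reduction)))
    stop("true_reduction needs named entries m1_m3, m3_m6, m6_m12")
  true_reduction <- true_reduction[.interval_names]
  if (any(true_reduction <= 0 | true_reduction >= 1))
    stop("net reductions must lie in (0, 1)")
  if (delayed_onset_prob < 0 || delayed_onset_prob >= 1)
    stop("delayed_onset_prob must be in [0, 1)")
  if (r_true <= 0 || r_true >= 1) stop("r_true must be in (0, 1)")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  if (!all(as.character(.canonical_months) %in% names(sympt_means)))
    stop("sympt_means needs entries named '1', '3', '6', '12'")
  if (sympt_sd <= 0) stop("sympt_sd must be > 0")
  known <- c("mean_age", "pct_male", "measure_type", "acute_timing")
  if (length(moderator_effects) > 0 &&
      !all(names(moderator_effects) %in% known))
    stop("moderator_effects names must be among: ",
         paste(known, collapse = ", "))
  structure(
    list(k = as.integer(k), n_range = as.integer(n_range),
         months = months, mu_logit = mu_logit, tau = tau,
         true_reduction = true_reduction, tau_reduction = tau_reduction,
         delayed_onset_prob = delayed_onset_prob, r_true = r_true,
         sympt_means = sympt_means[as.character(.canonical_months)],
         sympt_sd = sympt_sd, dropout_rate = dropout_rate,
         dropout_informative = isTRUE(dropout_informative),
         moderator_effects = moderator_effects, seed = as.integer(seed)),
    class = "sim_truth")
}

#' Generating values implied by a simulation truth
#'
#' `implied_prevalence()` returns the prevalence targeted by logit-scale
#' pooling at a month (exact at month 1, where the study logit
#' prevalences are symmetric around `mu_logit`; at later months the net
#' reduction chain is applied to the month-1 value). `implied_reduction()`
#' composes the net per-interval reductions over a frame:
#' \eqn{1 - \prod (1 - net_j)}. `implied_smc()` is the true standardized
#' mean change over a frame.
#'
#' @param truth A `sim_truth`.
#' @param month Nominal month.
#' @param frame Ascending pair of nominal months.
#' @return A single number on the proportion (or d) scale.
#' @export
implied_prevalence <- function(truth, month = 1) {
  stopifnot(inherits(truth, "sim_truth"), month %in% .canonical_months)
  p <- expit(truth$mu_logit)
  if (month > 1) p <- p * (1 - implied_reduction(truth, c(1, month)))
  p
}

#' @rdname implied_prevalence
#' @export
implied_reduction <- function(truth, frame = c(1, 6)) {
  stopifnot(inherits(truth, "sim_truth"), length(frame) == 2,
            all(frame %in% .canonical_months), frame[1] < frame[2])
  idx <- seq(match(frame[1], .canonical_months),
             match(frame[2], .canonical_months) - 1)
  1 - prod(1 - truth$true_reduction[idx])
}

#' @rdname implied_prevalence
#' @export
implied_smc <- function(truth, frame = c(1, 6)) {
  stopifnot(inherits(truth, "sim_truth"), length(frame) == 2,
            all(frame %in% .canonical_months), frame[1] < frame[2])
  m <- truth$sympt_means[as.character(frame)]
  as.numeric((m[1] - m[2]) / truth$sympt_sd)
}

# Deterministic per-study / per-replicate substream seeds below 2^31.
substream_seed <- function(master, index, stride = 10007L) {
  as.integer((as.numeric(master) + as.numeric(index) * stride) %%
               2147483647)
}

#' Simulate one study of the synthetic corpus
#'
#' Draws a study of `n` children (uniform on `n_range`) with study-level
#' moderators; the study's month-1 logit prevalence is
#' `mu_logit + moderator terms + N(0, tau)`. Children then follow a
#' near-monotone diagnosis process over the canonical waves 1, 3, 6, 12:
#' cases recover with a per-interval probability calibrated (against the
#' study's realized case count) so the *net* expected relative reduction
#' equals the truth, and non-cases newly meet criteria with probability
#' `delayed_onset_prob`. Symptom scores are equicorrelated normal within
#' child; dropout is monotone per follow-up wave. Observed waves are
#' aggregated to per-wave counts and moments.
#'
#' @param truth A [sim_truth()].
#' @param study_index Index used both as label and as substream selector;
#'   the call is deterministic given `(truth, study_index, seed)`.
#' @param seed Master seed (defaults to `truth$seed`).
#' @param return_children If `TRUE`, the child-level trajectories are
#'   attached as attribute `"children"` (list with the diagnosis `status`
#'   matrix over canonical waves, the `present` matrix over observed
#'   waves, and the symptom `scores` matrix), for inspecting the
#'   generating process directly.
#' @return A validated [study_record()].
#' @export
simulate_study <- function(truth, study_index, seed = truth$seed,
                           return_children = FALSE) {
  stopifnot(inherits(truth, "sim_truth"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(seed, study_index))

  n <- truth$n_range[1] +
    sample.int(truth$n_range[2] - truth$n_range[1] + 1L, 1) - 1L
  mean_age <- round(stats::runif(1, 9, 17), 1)
  pct_male <- round(stats::runif(1, 40, 80))
  measure_type <- stats::rbinom(1, 1, 0.25)
  acute_timing <- if (1L %in% truth$months) stats::rbinom(1, 1, 0.5)
                  else NA_integer_
  trauma_type <- sample(c("accidental_injury", "natural_disaster",
                          "assault"), 1, prob = c(0.8, 0.1, 0.1))

  centers <- c(mean_age = 13, pct_male = 60, measure_type = 0.25,
               acute_timing = 0.5)
  vals <- c(mean_age = mean_age, pct_male = pct_male,
            measure_type = measure_type,
            acute_timing = ifelse(is.na(acute_timing), 0.5,
                                  acute_timing))
  mod_shift <- 0
  for (nm in names(truth$moderator_effects))
    mod_shift <- mod_shift +
      truth$moderator_effects[[nm]] * (vals[[nm]] - centers[[nm]])
  eta1 <- truth$mu_logit + mod_shift + stats::rnorm(1, 0, truth$tau)
  p1 <- expit(eta1)

  # study-level fast/slow recovery effect, shared across intervals
  z_rec <- stats::rnorm(1, 0, truth$tau_reduction)
  net <- expit(logit(truth$true_reduction) + z_rec)

  nm_canon <- .canonical_months
  status <- matrix(NA_integer_, n, length(nm_canon))
  status[, 1] <- stats::rbinom(n, 1, p1)
  d_on <- truth$delayed_onset_prob
  for (j in 1:(length(nm_canon) - 1)) {
    cur <- status[, j]
    ncase <- sum(cur)
    # calibrate per-child recovery so E[cases_{j+1} | cases_j] hits the
    # net target despite delayed-onset inflow
    rec <- if (ncase > 0)
      min(1, max(0, net[j] + d_on * (n - ncase) / ncase)) else 0
    nxt <- integer(n)
    nxt[cur == 1] <- stats::rbinom(ncase, 1, 1 - rec)
    nxt[cur == 0] <- stats::rbinom(n - ncase, 1, d_on)
    status[, j + 1] <- nxt
  }

  # equicorrelated symptom scores: shared child factor + wave noise
  zc <- stats::rnorm(n)
  r <- truth$r_true
  scores <- sapply(seq_along(nm_canon), function(j)
    truth$sympt_means[j] + truth$sympt_sd *
      (sqrt(r) * zc + sqrt(1 - r) * stats::rnorm(n)))

  obs_months <- truth$months
  present <- matrix(TRUE, n, length(obs_months))
  if (length(obs_months) > 1) {
    for (j in 2:length(obs_months)) {
      jc <- match(obs_months[j - 1], nm_canon)
      p_drop <- rep(truth$dropout_rate, n)
      if (truth$dropout_informative)
        p_drop <- pmin(0.9, p_drop * (1 + status[, jc]))
      present[, j] <- present[, j - 1] & (stats::runif(n) >= p_drop)
    }
  }

  waves <- do.call(rbind, lapply(seq_along(obs_months), function(j) {
    jc <- match(obs_months[j], nm_canon)
    idx <- present[, j]
    win <- .wave_windows[.wave_windows$nominal_month == obs_months[j], ]
    data.frame(nominal_month = obs_months[j],
               actual_weeks = round(stats::runif(1, win$lo_weeks,
                                                 win$hi_weeks), 1),
               n_assessed = sum(idx),
               n_ptsd = sum(status[idx, jc]),
               sympt_mean = mean(scores[idx, jc]),
               sympt_sd = stats::sd(scores[idx, jc]))
  }))

  rec <- study_record(
    study_id = sprintf("sim%03d", study_index), n_baseline = n,
    mean_age = mean_age, pct_male = pct_male,
    measure_type = measure_type, acute_timing = acute_timing,
    trauma_type = trauma_type, informant = "child", waves = waves)
  if (return_children)
    attr(rec, "children") <- list(status = status, present = present,
                                  scores = scores)
  rec
}

#' Simulate a whole multi-study corpus with its truth
#'
#' @param truth A [sim_truth()].
#' @return List with `corpus` (a validated `ptsd_corpus`, provenance
#'   `"synthetic"`) and `truth`.
#' @examples
#' sim <- simulate_corpus(sim_truth(k = 3, seed = 7))
#' sim$corpus
#' @export
simulate_corpus <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  studies <- lapply(seq_len(truth$k), function(i)
    simulate_study(truth, i))
  corpus <- new_corpus(studies, provenance = "synthetic",
                       seed = truth$seed)
  list(corpus = corpus, truth = truth)
}

#' Monte-Carlo parameter-recovery experiment
#'
#' Repeatedly simulates corpora from a known truth, runs one pooled
#' analysis per replicate, and summarises recovery of the generating
#' value: mean estimate, bias, RMSE, 95\% CI coverage of the truth and
#' mean I2. Coverage is judged on the back-transformed (proportion or d)
#' scale; because the back-transform is monotone this is equivalent to
#' judging it on the working scale.
#'
#' @param truth A [sim_truth()].
#' @param n_reps Number of replicates (>= 100 recommended for coverage
#'   claims).
#' @param type `"point_prevalence"`, `"reduction"` or `"smc"`.
#' @param month Nominal month (point prevalence).
#' @param frame Month pair (change analyses).
#' @param variant Attrition variant (reduction).
#' @param r_assumed Assumed correlation (smc).
#' @return An object of class `recovery_report`.
#' @export
recovery_experiment <- function(truth, n_reps = 500,
                                type = c("point_prevalence", "reduction",
                                         "smc"),
                                month = 1, frame = c(1, 6),
                                variant = "mcar", r_assumed = 0.6) {
  stopifnot(inherits(truth, "sim_truth"), n_reps >= 1)
  type <- match.arg(type)
  target <- switch(type,
                   point_prevalence = implied_prevalence(truth, month),
                   reduction = implied_reduction(truth, frame),
                   smc = implied_smc(truth, frame))
  est <- lo <- hi <- i2 <- numeric(n_reps)
  for (rep in seq_len(n_reps)) {
    t_rep <- truth
    t_rep$seed <- substream_seed(truth$seed, rep, stride = 104729L)
    corpus <- simulate_corpus(t_rep)$corpus
    res <- switch(type,
      point_prevalence = pool_point_prevalence(corpus, month),
      reduction = pool_reduction(corpus, frame, variant = variant),
      smc = pool_symptom_change(corpus, frame, r_assumed = r_assumed))
    est[rep] <- res$estimate_bt
    lo[rep] <- res$ci_lo_bt
    hi[rep] <- res$ci_hi_bt
    i2[rep] <- res$i2
  }
  structure(
    list(type = type, month = month, frame = frame, truth_value = target,
         n_reps = n_reps, estimates = est,
         mean_estimate = mean(est), bias = mean(est) - target,
         rmse = sqrt(mean((est - target)^2)),
         coverage = mean(lo <= target & target <= hi),
         mean_i2 = mean(i2, na.rm = TRUE)),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  lab <- if (x$type == "point_prevalence") paste0("month ", x$month)
         else paste0("frame ", frame_label(x$frame))
  cat(sprintf("<recovery_report> %s, %s (%d reps)\n", x$type, lab,
              x$n_reps))
  cat(sprintf("  truth %.4f | mean estimate %.4f | bias %+.4f | RMSE %.4f\n",
              x$truth_value, x$mean_estimate, x$bias, x$rmse))
  cat(sprintf("  95%% CI coverage %.1f%% | mean I2 %.1f%%\n",
              100 * x$coverage, x$mean_i2))
  invisible(x)
}
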