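# Univariable random-effects meta-regression (REML residual tau^2,
# Knapp-Hartung inference) and funnel-based small-study diagnostics.

# Restricted log-likelihood of the one-covariate mixed-effects model at a
# given residual tau^2, up to an additive constant.
reml_ll <- function(tau2, y, s2, X) {
  v <- s2 + tau2
  w <- 1 / v
  XtWX <- crossprod(X, w * X)
  b <- solve(XtWX, crossprod(X, w * y))
  r <- y - X %*% b
  -0.5 * (sum(log(v)) +
            as.numeric(determinant(XtWX, logarithm = TRUE)$modulus) +
            sum(w * r^2))
}

#' Univariable random-effects meta-regression
#'
#' Regresses study effect sizes on a single moderator under the
#' mixed-effects model \eqn{y_i = \beta_0 + \beta_1 x_i + u_i + e_i} with
#' \eqn{u_i \sim N(0, \tau^2)} and known within-study variances. The
#' residual \eqn{\tau^2} is estimated by REML (profiled numerically);
#' inference on the slope uses the Knapp-Hartung adjustment: the
#' weighted-least-squares covariance is rescaled by the standardized
#' residual sum of squares over `k - 2`, and the p-value comes from a t
#' distribution with `k - 2` degrees of freedom. The small-sample
#' calibration of the type-I error rate is the reason for the adjustment.
#'
#' Studies with a missing moderator value are dropped (pairwise).
#'
#' @param effects An `effect_set` or effect-size data frame (needs
#'   `estimate`, `se`, `study_id`).
#' @param moderator Numeric covariate, one value per effect row (aligned).
#' @param moderator_name Name carried into reports.
#' @param label Analysis label.
#' @return An object of class `metareg_result`: `analysis_label`,
#'   `moderator_name`, `k`, `slope`, `se_kh`, `p_value`, `tau2_resid`,
#'   `intercept`, `intercept_se_kh`.
#' @export
fit_metareg <- function(effects, moderator, moderator_name = "moderator",
                        label = "") {
  if (inherits(effects, "effect_set")) {
    if (label == "")
      label <- paste0(effects$scale, "_", frame_label(effects$frame))
    effects <- effects$effects
  }
  stopifnot(is.data.frame(effects),
            length(moderator) == nrow(effects))
  keep <- !is.na(moderator) & !is.na(effects$estimate)
  y <- effects$estimate[keep]
  s2 <- effects$se[keep]^2
  x <- as.numeric(moderator[keep])
  k <- length(y)
  if (k < 3) stop("meta-regression needs k >= 3 studies, got ", k)
  if (stats::var(x) == 0) stop("no variance in moderator '",
                               moderator_name, "'")

  X <- cbind(intercept = 1, x)
  upper <- max(10 * stats::var(y), 1e-3)
  opt <- stats::optimize(reml_ll, c(0, upper), maximum = TRUE,
                         tol = 1e-9, y = y, s2 = s2, X = X)
  tau2 <- if (reml_ll(0, y, s2, X) >= opt$objective) 0 else opt$maximum

  w <- 1 / (s2 + tau2)
  XtWX <- crossprod(X, w * X)
  b <- solve(XtWX, crossprod(X, w * y))
  r <- y - X %*% b
  # Knapp-Hartung: rescale the WLS covariance by the standardized RSS.
  q_kh <- sum(w * r^2) / (k - 2)
  vb <- q_kh * solve(XtWX)
  se_kh <- sqrt(vb[2, 2])
  tstat <- b[2] / se_kh
  structure(
    list(analysis_label = label, moderator_name = moderator_name, k = k,
         slope = as.numeric(b[2]), se_kh = se_kh,
         p_value = 2 * stats::pt(abs(tstat), df = k - 2,
                                 lower.tail = FALSE),
         tau2_resid = tau2, intercept = as.numeric(b[1]),
         intercept_se_kh = sqrt(vb[1, 1])),
    class = "metareg_result")
}

#' @export
print.metareg_result <- function(x, ...) {
  cat(sprintf("<metareg_result> %s ~ %s (k = %d)\n", x$analysis_label,
              x$moderator_name, x$k))
  cat(sprintf("  slope %.4f (KH se %.4f), t-based p = %.4f, tau2_resid = %.4f\n",
              x$slope, x$se_kh, x$p_value, x$tau2_resid))
  invisible(x)
}

#' @export
as.data.frame.metareg_result <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(analysis = x$analysis_label, moderator = x$moderator_name,
             k = x$k, slope = x$slope, se = x$se_kh, p = x$p_value,
             tau2_resid = x$tau2_resid, intercept = x$intercept,
             stringsAsFactors = FALSE)
}

# Moderator values aligned to the studies of an effect set. For change
# analyses, initial_prevalence is the observed case proportion at the
# frame's first wave.
moderator_values <- function(corpus, es, name) {
  ids <- es$effects$study_id
  vapply(ids, function(id) {
    s <- corpus$studies[[id]]
    switch(name,
           mean_age = s$mean_age,
           pct_male = s$pct_male,
           measure_type = as.numeric(s$measure_type),
           acute_timing = as.numeric(s$acute_timing),
           initial_prevalence = {
             w1 <- s$waves[s$waves$nominal_month == es$frame[1], ,
                           drop = FALSE]
             if (nrow(w1) == 1 && !is.na(w1$n_ptsd))
               w1$n_ptsd / w1$n_assessed else NA_real_
           },
           stop("unknown moderator: ", name))
  }, numeric(1))
}

#' Screen the prespecified moderators for one analysis
#'
#' Fits one univariable meta-regression per applicable moderator,
#' following the prespecified applicability rules: mean age and
#' proportion of boys apply everywhere; PTSD measurement type
#' (self-report cut-off vs diagnostic interview) applies to
#' prevalence-based analyses only; initial PTSD prevalence applies to
#' change analyses only; acute-assessment timing (< 4 weeks vs 4--6
#' weeks) applies only to analyses involving the 1-month wave.
#' Inapplicable moderators, and moderators whose fit fails (too few
#' studies, no variance), are listed in the skip report with the reason.
#'
#' @param corpus A `ptsd_corpus`.
#' @param type `"point_prevalence"`, `"reduction"` or `"smc"`.
#' @param month Nominal month (point prevalence only).
#' @param frame Month pair (change analyses only).
#' @param variant Attrition variant for reduction analyses.
#' @param r_assumed Assumed correlation for smc analyses.
#' @return List with `results` (list of `metareg_result`) and `skipped`
#'   (data frame `moderator`, `reason`).
#' @export
moderator_screen <- function(corpus,
                             type = c("point_prevalence", "reduction",
                                      "smc"),
                             month = 1, frame = c(1, 6),
                             variant = "mcar", r_assumed = 0.6) {
  type <- match.arg(type)
  es <- switch(type,
    point_prevalence = build_effects_for_frame(corpus, month,
                                               "logit_prevalence"),
    reduction = build_effects_for_frame(corpus, frame, "logit_reduction",
                                        variant = variant),
    smc = build_effects_for_frame(corpus, frame, "smc",
                                  r_assumed = r_assumed))
  label <- paste0(es$scale, "_", frame_label(es$frame))
  involves_month1 <- if (type == "point_prevalence") month == 1
                     else frame[1] == 1

  all_mods <- c("mean_age", "pct_male", "measure_type", "acute_timing",
                "initial_prevalence")
  results <- list()
  skipped <- list()
  skip <- function(mod, reason)
    skipped[[length(skipped) + 1]] <<- data.frame(
      moderator = mod, reason = reason, stringsAsFactors = FALSE)

  for (mod in all_mods) {
    if (mod == "measure_type" && type == "smc") {
      skip(mod, "prevalence-based analyses only"); next
    }
    if (mod == "initial_prevalence" && type == "point_prevalence") {
      skip(mod, "change analyses only"); next
    }
    if (mod == "acute_timing" && !involves_month1) {
      skip(mod, "analyses involving the 1-month wave only"); next
    }
    x <- moderator_values(corpus, es, mod)
    fit <- tryCatch(fit_metareg(es, x, moderator_name = mod,
                                label = label),
                    error = function(e) conditionMessage(e))
    if (is.character(fit)) skip(mod, fit)
    else results[[mod]] <- fit
  }
  list(results = results,
       skipped = if (length(skipped) > 0) do.call(rbind, skipped)
                 else data.frame(moderator = character(0),
                                 reason = character(0),
                                 stringsAsFactors = FALSE))
}

#' Funnel-plot data and Egger regression for small-study asymmetry
#'
#' Emits the (estimate, se) pairs of a funnel plot together with the
#' Egger regression test: the standardized effect `y/se` is regressed on
#' precision `1/se`, and the intercept is tested against zero with a t
#' test on `k - 2` degrees of freedom. Under funnel symmetry the
#' intercept is near zero. The numeric Egger test supplements the visual
#' funnel inspection the analysis design calls for.
#'
#' @param effects An `effect_set` or effect-size data frame (k >= 3).
#' @param label Analysis label.
#' @return An object of class `funnel_diagnostics`: `analysis_label`,
#'   `points` (data frame `study_id`, `estimate`, `se`),
#'   `egger_intercept`, `egger_se`, `egger_p`.
#' @export
funnel_diagnostics <- function(effects, label = "") {
  if (inherits(effects, "effect_set")) {
    if (label == "")
      label <- paste0(effects$scale, "_", frame_label(effects$frame))
    effects <- effects$effects
  }
  k <- nrow(effects)
  if (k < 3) stop("funnel diagnostics need k >= 3 studies, got ", k)
  z <- effects$estimate / effects$se
  prec <- 1 / effects$se
  fit <- stats::lm(z ~ prec)
  sm <- summary(fit)$coefficients
  structure(
    list(analysis_label = label,
         points = data.frame(study_id = effects$study_id,
                             estimate = effects$estimate,
                             se = effects$se, stringsAsFactors = FALSE),
         egger_intercept = sm[1, 1], egger_se = sm[1, 2],
         egger_p = sm[1, 4]),
    class = "funnel_diagnostics")
}

#' @export
print.funnel_diagnostics <- function(x, ...) {
  cat(sprintf("<funnel_diagnostics> %s (k = %d)\n", x$analysis_label,
              nrow(x$points)))
  cat(sprintf("  Egger intercept %.3f (se %.3f), p = %.4f\n",
              x$egger_intercept, x$egger_se, x$egger_p))
  invisible(x)
}
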