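#' DerSimonian-Laird random-effects pooling
#'
#' Pools a set of study effect sizes sharing one working scale with the
#' DerSimonian-Laird method-of-moments estimator. With fixed-effect
#' weights \eqn{w_i = 1/se_i^2}, Cochran's
#' \eqn{Q = \sum w_i (y_i - \bar y_{FE})^2} with \eqn{df = k - 1},
#' \eqn{\tau^2 = \max(0, (Q - df)/C)} where
#' \eqn{C = \sum w_i - \sum w_i^2 / \sum w_i}, random-effects weights
#' \eqn{1/(se_i^2 + \tau^2)}, a normal-theory 95\% CI, and
#' \eqn{I^2 = \max(0, (Q - df)/Q) \times 100}. With a single study the
#' pooled result is the study itself (\eqn{\tau^2 = 0}, `df = 0`, `I2`
#' not applicable).
#'
#' @param effects An `effect_set` from [build_effects_for_frame()] or a
#'   data frame with columns `study_id`, `scale`, `estimate`, `se`.
#' @param label Analysis label carried into reports.
#' @return An object of class `pooled_result`: `analysis_label`, `scale`,
#'   `k`, `estimate`, `se`, `ci_lo`, `ci_hi`, `Q`, `df`, `tau2`, `i2`,
#'   back-transformed fields (filled by [back_transform()]), and a
#'   `studies` data frame with random-effects weights.
#' @examples
#' eff <- data.frame(study_id = c("a", "b", "c"), scale = "smc",
#'                   estimate = c(0, 1, 2), se = 0.5)
#' dl_pool(eff)  # Q = 8, tau2 = 0.75, I2 = 75
#' @export
dl_pool <- function(effects, label = "") {
  if (inherits(effects, "effect_set")) {
    if (label == "")
      label <- paste0(effects$scale, "_", frame_label(effects$frame))
    effects <- effects$effects
  }
  stopifnot(is.data.frame(effects),
            all(c("study_id", "scale", "estimate", "se") %in%
                  names(effects)))
  k <- nrow(effects)
  if (k == 0) stop("no effects to pool")
  scale <- unique(effects$scale)
  if (length(scale) != 1)
    stop("mixed scales in one pooling: ", paste(scale, collapse = ", "))
  if (any(effects$se <= 0)) stop("all standard errors must be > 0")

  y <- effects$estimate
  s2 <- effects$se^2
  w <- 1 / s2
  y_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - y_fe)^2)
  df <- k - 1
  if (df > 0) {
    C <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (Q - df) / C)
    i2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  } else {
    tau2 <- 0
    i2 <- NA_real_
  }
  w_re <- 1 / (s2 + tau2)
  est <- sum(w_re * y) / sum(w_re)
  se <- sqrt(1 / sum(w_re))
  z <- stats::qnorm(0.975)

  structure(
    list(analysis_label = label, scale = scale, k = k,
         estimate = est, se = se,
         ci_lo = est - z * se, ci_hi = est + z * se,
         estimate_bt = NA_real_, ci_lo_bt = NA_real_, ci_hi_bt = NA_real_,
         Q = Q, df = df, tau2 = tau2, i2 = i2,
         studies = data.frame(
           study_id = effects$study_id, estimate = y, se = effects$se,
           re_weight_pct = 100 * w_re / sum(w_re),
           stringsAsFactors = FALSE)),
    class = "pooled_result")
}

#' Back-transform a pooled logit-scale result to proportions
#'
#' Logit-scale summaries (point prevalence, prevalence reduction) are
#' inverse-logit transformed back to proportions for interpretation; the
#' transform is monotone, so CI bound order is preserved. Results on the
#' `smc` (d) scale pass through unchanged.
#'
#' @param result A `pooled_result`.
#' @return The `pooled_result` with `estimate_bt`, `ci_lo_bt`, `ci_hi_bt`
#'   filled.
#' @export
back_transform <- function(result) {
  stopifnot(inherits(result, "pooled_result"))
  f <- if (result$scale %in% c("logit_prevalence", "logit_reduction"))
    expit else identity
  result$estimate_bt <- f(result$estimate)
  result$ci_lo_bt <- f(result$ci_lo)
  result$ci_hi_bt <- f(result$ci_hi)
  result
}

pool_effect_set <- function(es, label) {
  res <- back_transform(dl_pool(es, label = label))
  res$skipped <- es$skipped
  res
}

#' Pooled point prevalence of PTSD at one nominal month
#'
#' Builds the per-study logit point-prevalence effects at `month`, pools
#' them by DerSimonian-Laird, and back-transforms to a proportion.
#'
#' @param corpus A `ptsd_corpus`.
#' @param month Nominal posttrauma month (1, 3, 6 or 12).
#' @return A `pooled_result`; `estimate_bt` is the pooled prevalence.
#' @export
pool_point_prevalence <- function(corpus, month) {
  es <- build_effects_for_frame(corpus, month, "logit_prevalence")
  pool_effect_set(es, sprintf("prevalence_month%d", as.integer(month)))
}

#' Pooled relative prevalence reduction between two months
#'
#' @param corpus A `ptsd_corpus`.
#' @param frame Ascending pair of nominal months, e.g. `c(1, 6)`.
#' @param variant Attrition assumption; see [impute_t2_cases()].
#' @return A `pooled_result`; `estimate_bt` is the pooled proportion of
#'   initial cases who lost the diagnosis.
#' @export
pool_reduction <- function(corpus, frame, variant = "mcar") {
  es <- build_effects_for_frame(corpus, frame, "logit_reduction",
                                variant = variant)
  pool_effect_set(es, sprintf("reduction_%s_%s", frame_label(frame),
                              variant))
}

#' Pooled standardized mean symptom change between two months
#'
#' When `r_assumed` is `NULL` the analysis is run for each assumed
#' pre-post correlation in `r_values` and a named list is returned; the
#' pooled point estimate is identical across the grid (only CI widths
#' differ), which is the basis of the correlation sensitivity analysis.
#'
#' @param corpus A `ptsd_corpus`.
#' @param frame Ascending pair of nominal months.
#' @param r_assumed Single assumed correlation in (0, 1), or `NULL` for
#'   the full grid.
#' @param r_values Correlation grid used when `r_assumed` is `NULL`.
#' @return A `pooled_result`, or a named list of them over the grid.
#' @export
pool_symptom_change <- function(corpus, frame, r_assumed = NULL,
                                r_values = c(0.2, 0.4, 0.6, 0.8)) {
  if (!is.null(r_assumed)) {
    es <- build_effects_for_frame(corpus, frame, "smc",
                                  r_assumed = r_assumed)
    return(pool_effect_set(es, sprintf("smc_%s_r%s", frame_label(frame),
                                       r_assumed)))
  }
  out <- lapply(r_values, function(r)
    pool_symptom_change(corpus, frame, r_assumed = r))
  names(out) <- paste0("r=", r_values)
  out
}

#' Per-study forest-plot data for a pooled analysis
#'
#' The numeric content of a forest plot: back-transformed study
#' estimates, 95\% CIs and random-effects weights.
#'
#' @param result A `pooled_result`.
#' @return Data frame `study_id`, `estimate_bt`, `ci_lo_bt`, `ci_hi_bt`,
#'   `re_weight_pct`.
#' @export
forest_data <- function(result) {
  stopifnot(inherits(result, "pooled_result"))
  f <- if (result$scale %in% c("logit_prevalence", "logit_reduction"))
    expit else identity
  z <- stats::qnorm(0.975)
  s <- result$studies
  data.frame(study_id = s$study_id,
             estimate_bt = f(s$estimate),
             ci_lo_bt = f(s$estimate - z * s$se),
             ci_hi_bt = f(s$estimate + z * s$se),
             re_weight_pct = s$re_weight_pct,
             stringsAsFactors = FALSE)
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("<pooled_result> %s (k = %d)\n", x$analysis_label, x$k))
  cat(sprintf("  %s scale: %.4f [%.4f, %.4f]\n", x$scale, x$estimate,
              x$ci_lo, x$ci_hi))
  if (!is.na(x$estimate_bt) &&
      x$scale %in% c("logit_prevalence", "logit_reduction"))
    cat(sprintf("  back-transformed: %.3f [%.3f, %.3f]\n", x$estimate_bt,
                x$ci_lo_bt, x$ci_hi_bt))
  cat(sprintf("  Q = %.3f (df = %d), tau2 = %.4f, I2 = %s\n", x$Q, x$df,
              x$tau2,
              if (is.na(x$i2)) "n/a" else sprintf("%.1f%%", x$i2)))
  invisible(x)
}

#' Flatten a pooled result to a one-row summary table
#'
#' @param x A `pooled_result`.
#' @param row.names,optional,... Ignored.
#' @return One-row data frame with columns `analysis`, `k`, `estimate`,
#'   `ci_lo`, `ci_hi`, `Q`, `df`, `tau2`, `i2`, then the back-transformed
#'   columns and `se`.
#' @export
as.data.frame.pooled_result <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(analysis = x$analysis_label, k = x$k, estimate = x$estimate,
             ci_lo = x$ci_lo, ci_hi = x$ci_hi, Q = x$Q, df = x$df,
             tau2 = x$tau2, i2 = x$i2, estimate_bt = x$estimate_bt,
             ci_lo_bt = x$ci_lo_bt, ci_hi_bt = x$ci_hi_bt, se = x$se,
             scale = x$scale, stringsAsFactors = FALSE)
}
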