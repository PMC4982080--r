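test_that("meta-regression matches metafor's REML + Knapp-Hartung fit", {
  set.seed(10)
  k <- 12
  x <- runif(k, 8, 16)
  y <- -1.3 + 0.1 * x + rnorm(k, 0, 0.4)
  se <- runif(k, 0.15, 0.45)
  eff <- data.frame(study_id = paste0("s", 1:k),
                    scale = "logit_prevalence", estimate = y, se = se)
  fit <- fit_metareg(eff, x, moderator_name = "mean_age")
  m <- metafor::rma(yi = y, sei = se, mods = ~x, method = "REML",
                    test = "knha")
  expect_equal(fit$tau2_resid, m$tau2, tolerance = 1e-4)
  expect_equal(fit$slope, as.numeric(m$beta[2]), tolerance = 1e-6)
  expect_equal(fit$intercept, as.numeric(m$beta[1]), tolerance = 1e-6)
  expect_equal(fit$se_kh, m$se[2], tolerance = 1e-6)
  expect_equal(fit$p_value, m$pval[2], tolerance = 1e-6)
  expect_equal(fit$k, k)
})

test_that("meta-regression rejects degenerate inputs", {
  eff <- data.frame(study_id = letters[1:5], scale = "smc",
                    estimate = rnorm(5), se = rep(0.2, 5))
  expect_error(fit_metareg(eff[1:2, ], c(1, 2)), "k >= 3")
  expect_error(fit_metareg(eff, rep(1, 5)), "no variance")
  # constant after NA exclusion
  expect_error(fit_metareg(eff, c(0, 0, 0, 0, NA)), "no variance")
})

test_that("intercept on a centered moderator approximates the pooled estimate", {
  set.seed(21)
  k <- 20
  y <- rnorm(k, 0.4, 0.3)
  se <- runif(k, 0.1, 0.3)
  x <- rnorm(k)
  eff <- data.frame(study_id = paste0("s", 1:k), scale = "smc",
                    estimate = y, se = se)
  fit <- fit_metareg(eff, x - mean(x))
  pooled <- dl_pool(eff)
  expect_lt(abs(fit$intercept - pooled$estimate), 0.05)
})

test_that("moderator screens follow the prespecified applicability rules", {
  corpus <- simulate_corpus(sim_truth(k = 10, seed = 31))$corpus

  scr <- moderator_screen(corpus, "point_prevalence", month = 3)
  expect_true(all(c("mean_age", "pct_male", "measure_type") %in%
                    names(scr$results)))
  expect_true("acute_timing" %in% scr$skipped$moderator)
  expect_true("initial_prevalence" %in% scr$skipped$moderator)

  scr <- moderator_screen(corpus, "reduction", frame = c(3, 6))
  expect_true("initial_prevalence" %in% names(scr$results))
  expect_true("acute_timing" %in% scr$skipped$moderator)

  scr <- moderator_screen(corpus, "smc", frame = c(1, 6))
  expect_true("measure_type" %in% scr$skipped$moderator)
  expect_match(
    scr$skipped$reason[scr$skipped$moderator == "measure_type"],
    "prevalence-based")
  expect_true("acute_timing" %in% names(scr$results) ||
                "acute_timing" %in% scr$skipped$moderator)
})

test_that("a generated moderator effect is recovered with the right sign", {
  hits <- 0
  for (seed in 1:20) {
    truth <- sim_truth(k = 20, moderator_effects = c(mean_age = 0.25),
                      seed = 1000 + seed)
    corpus <- simulate_corpus(truth)$corpus
    es <- build_effects_for_frame(corpus, 1, "logit_prevalence")
    x <- sapply(es$effects$study_id,
                function(id) corpus$studies[[id]]$mean_age)
    fit <- fit_metareg(es, x, "mean_age")
    if (fit$slope > 0) hits <- hits + 1
  }
  expect_gte(hits, 18)  # sign recovered in > 90% of replicates
})

test_that("funnel diagnostics need k >= 3 and report Egger terms", {
  eff <- data.frame(study_id = c("a", "b"), scale = "smc",
                    estimate = c(0, 1), se = c(0.1, 0.2))
  expect_error(funnel_diagnostics(eff), "k >= 3")

  set.seed(5)
  eff <- data.frame(study_id = paste0("s", 1:10), scale = "smc",
                    estimate = rnorm(10, 0.4, 0.2),
                    se = runif(10, 0.1, 0.4))
  fd <- funnel_diagnostics(eff, label = "demo")
  expect_equal(nrow(fd$points), 10)
  expect_true(is.finite(fd$egger_intercept) && is.finite(fd$egger_p))
})

test_that("the Egger t-statistic is invariant to a common rescaling", {
  set.seed(6)
  eff <- data.frame(study_id = paste0("s", 1:8), scale = "smc",
                    estimate = rnorm(8, 0.3, 0.25),
                    se = runif(8, 0.1, 0.5))
  f1 <- funnel_diagnostics(eff)
  eff2 <- transform(eff, estimate = 3 * estimate, se = 3 * se)
  f2 <- funnel_diagnostics(eff2)
  expect_equal(f1$egger_intercept / f1$egger_se,
               f2$egger_intercept / f2$egger_se, tolerance = 1e-10)
  expect_equal(f1$egger_p, f2$egger_p, tolerance = 1e-10)
})

test_that("a symmetric funnel rarely triggers Egger; a censored one does", {
  # classical funnel: sampling noise equals the study SE
  set.seed(8)
  n_sig <- 0
  reps <- 100
  for (i in 1:reps) {
    k <- 15
    se <- runif(k, 0.1, 0.6)
    y <- rnorm(k, -1.3, se)
    eff <- data.frame(study_id = paste0("s", 1:k), scale = "logit_prevalence",
                      estimate = y, se = se)
    if (funnel_diagnostics(eff)$egger_p < 0.05) n_sig <- n_sig + 1
  }
  expect_lte(n_sig / reps, 0.12)  # near-nominal under symmetry

  # censor small high-prevalence studies: asymmetry, negative intercept
  # (the remaining small studies' standardized effects fall below the
  # line the large studies anchor)
  set.seed(9)
  n_detect <- 0; neg <- 0
  for (i in 1:40) {
    k <- 60
    se <- runif(k, 0.1, 0.8)
    y <- rnorm(k, -1.3, se)
    drop <- se > 0.3 & y > -1.3   # remove small high-prevalence studies
    eff <- data.frame(study_id = paste0("s", 1:k),
                      scale = "logit_prevalence",
                      estimate = y, se = se)[!drop, ]
    fd <- funnel_diagnostics(eff)
    if (fd$egger_p < 0.05) n_detect <- n_detect + 1
    if (fd$egger_intercept < 0) neg <- neg + 1
  }
  expect_gt(n_detect / 40, 0.5)
  expect_gt(neg / 40, 0.9)
})
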