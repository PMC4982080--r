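test_that("logit point prevalence matches direct arithmetic, with boundary correction", {
  e <- logit_prevalence_effect(50, 100)
  expect_equal(e$estimate, 0)
  expect_equal(e$se, sqrt(1 / 50 + 1 / 50))

  e <- logit_prevalence_effect(21, 100)
  expect_equal(e$estimate, log(21 / 79))
  expect_equal(e$se, sqrt(1 / 21 + 1 / 79))
  expect_identical(e$flags, "")

  # x = 0: both cells corrected (x' = 0.5, n' = 51), finite and flagged
  e <- logit_prevalence_effect(0, 50)
  expect_equal(e$estimate, log(0.5 / 50.5))
  expect_equal(e$se, sqrt(1 / 0.5 + 1 / 50.5))
  expect_match(e$flags, "continuity_applied")

  expect_error(logit_prevalence_effect(5, 0), "n")
})

test_that("attrition imputation follows the three dropout assumptions", {
  expect_equal(impute_t2_cases(20, 8, 80, 100, "mcar"), 12)
  expect_equal(impute_t2_cases(20, 8, 80, 100, "no_dropouts_ptsd"), 8)
  expect_equal(impute_t2_cases(20, 8, 80, 100, "all_dropouts_ptsd"), 28)
  # fractional totals are kept unrounded
  expect_equal(impute_t2_cases(21, 8, 80, 100, "mcar"), 8 + 20 * 0.21)
  expect_error(impute_t2_cases(20, 0, 0, 100, "mcar"), "m = 0")
})

test_that("prevalence reduction is logit-transformed with case-based SEs", {
  e <- prevalence_reduction_effect(20, 10, c(1, 6))
  expect_equal(e$estimate, 0)                      # R = 0.5
  expect_equal(e$se, sqrt(1 / 10 + 1 / 10))
  expect_equal(e$n_effective, 20)

  e <- prevalence_reduction_effect(20, 12, c(1, 6))
  expect_equal(e$estimate, log(0.4 / 0.6))

  expect_error(prevalence_reduction_effect(0, 5, c(1, 6)), "excluded")
})

test_that("no change in case counts receives the 1% substitution", {
  e <- prevalence_reduction_effect(10, 10, c(1, 3))
  expect_identical(e$estimate, logit(0.01))
  expect_match(e$flags, "continuity_applied")
  expect_match(e$flags, "clamped")
  # a prevalence increase is clamped to the same floor, flagged
  e2 <- prevalence_reduction_effect(10, 14, c(1, 3))
  expect_identical(e2$estimate, logit(0.01))
  # complete recovery clamps at the 99% ceiling
  e3 <- prevalence_reduction_effect(10, 0, c(1, 3))
  expect_identical(e3$estimate, logit(0.99))
})

test_that("reduction SE scales as 1/sqrt(n1) at fixed R", {
  e1 <- prevalence_reduction_effect(20, 10, c(1, 6))
  e2 <- prevalence_reduction_effect(80, 40, c(1, 6))
  expect_equal(e1$se / e2$se, 2)
})

test_that("standardized mean change has r-invariant estimate and r-monotone variance", {
  e <- symptom_change_effect(30, 10, 30, 10, n = 50, r_assumed = 0.6)
  expect_equal(e$estimate, 0)
  expect_equal(e$se^2, 2 * 0.4 / 50)

  e <- symptom_change_effect(30, 10, 25, 10, n = 50, r_assumed = 0.6)
  expect_equal(e$estimate, 0.5)
  expect_equal(e$se^2, 0.016 + 0.25 / 100)

  lo <- symptom_change_effect(30, 10, 25, 10, n = 50, r_assumed = 0.2)
  hi <- symptom_change_effect(30, 10, 25, 10, n = 50, r_assumed = 0.8)
  expect_equal(lo$estimate, hi$estimate)
  expect_equal(lo$se^2, 0.0345)
  expect_equal(hi$se^2, 0.0105)
  # variance strictly decreasing over the full grid
  vars <- sapply(c(0.2, 0.4, 0.6, 0.8), function(r)
    symptom_change_effect(30, 10, 25, 10, 50, r)$se^2)
  expect_true(all(diff(vars) < 0))

  expect_error(symptom_change_effect(30, 0, 25, 10, 50, 0.6), "deviations")
})

test_that("logit and expit are mutual inverses on (0,1)", {
  p <- seq(0.001, 0.999, length.out = 101)
  expect_equal(expit(logit(p)), p, tolerance = 1e-12)
  x <- seq(-8, 8, length.out = 101)
  expect_equal(logit(expit(x)), x, tolerance = 1e-9)
})

test_that("attrition variants are ordered study-wise over random corpora", {
  for (seed in c(11, 23, 57)) {
    corpus <- simulate_corpus(sim_truth(k = 8, dropout_rate = 0.3,
                                        seed = seed))$corpus
    eff <- lapply(c("all_dropouts_ptsd", "mcar", "no_dropouts_ptsd"),
                  function(v)
                    build_effects_for_frame(corpus, c(1, 6),
                                            "logit_reduction",
                                            variant = v)$effects)
    ids <- Reduce(intersect, lapply(eff, `[[`, "study_id"))
    for (id in ids) {
      y <- sapply(eff, function(d) d$estimate[d$study_id == id])
      expect_true(y[1] <= y[2] + 1e-12 && y[2] <= y[3] + 1e-12)
    }
  }
})

test_that("with zero attrition all imputation variants coincide", {
  corpus <- simulate_corpus(sim_truth(k = 6, dropout_rate = 0,
                                      seed = 5))$corpus
  eff <- lapply(c("mcar", "all_dropouts_ptsd", "no_dropouts_ptsd"),
                function(v)
                  build_effects_for_frame(corpus, c(1, 6),
                                          "logit_reduction",
                                          variant = v)$effects)
  expect_equal(eff[[1]]$estimate, eff[[2]]$estimate)
  expect_equal(eff[[1]]$estimate, eff[[3]]$estimate)
})

test_that("ineligible studies land in the skip report with a reason", {
  one_wave <- fixture_study("solo", data.frame(nominal_month = 1,
                                               n_assessed = 50,
                                               n_ptsd = 10))
  both <- fixture_study("pair", data.frame(nominal_month = c(1, 3),
                                           n_assessed = c(60, 50),
                                           n_ptsd = c(12, 9)))
  corpus <- longimeta:::new_corpus(list(one_wave, both))
  es <- build_effects_for_frame(corpus, c(1, 3), "logit_reduction")
  expect_equal(es$effects$study_id, "pair")
  expect_equal(es$skipped$study_id, "solo")
  expect_match(es$skipped$reason, "missing wave 3")

  expect_error(build_effects_for_frame(corpus, c(3, 6), "logit_reduction"),
               "3-6")
})
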