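test_that("every DL quantity matches the hand-computed three-study example", {
  eff <- data.frame(study_id = c("a", "b", "c"), scale = "smc",
                    estimate = c(0, 1, 2), se = 0.5)
  res <- dl_pool(eff, label = "hand")
  expect_equal(res$Q, 8, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$tau2, 0.75, tolerance = 1e-12)
  expect_equal(res$i2, 75, tolerance = 1e-12)
  expect_equal(res$estimate, 1, tolerance = 1e-12)
  expect_equal(res$se, sqrt(1 / 3), tolerance = 1e-12)
})

test_that("pooling one study returns the study itself", {
  res <- dl_pool(data.frame(study_id = "only", scale = "smc",
                            estimate = 0.3, se = 0.1))
  expect_equal(res$estimate, 0.3)
  expect_equal(res$tau2, 0)
  expect_equal(res$df, 0)
  expect_true(is.na(res$i2))
  expect_equal(res$ci_lo, 0.3 - qnorm(0.975) * 0.1)
  expect_equal(res$ci_hi, 0.3 + qnorm(0.975) * 0.1)
})

test_that("identical effects pool to the common value with zero heterogeneity", {
  eff <- data.frame(study_id = letters[1:3], scale = "smc",
                    estimate = 0.44, se = c(0.1, 0.2, 0.15))
  res <- dl_pool(eff)
  expect_equal(res$estimate, 0.44)
  expect_equal(res$Q, 0, tolerance = 1e-20)
  expect_equal(res$tau2, 0)
  expect_equal(res$i2, 0)
})

test_that("DL agrees with the brute-force oracle to 1e-10 on small fixtures", {
  set.seed(42)
  for (case in 1:25) {
    k <- sample(2:4, 1)
    y <- rnorm(k, 0, 1.5)
    se <- runif(k, 0.05, 0.8)
    res <- dl_pool(data.frame(study_id = paste0("s", 1:k), scale = "smc",
                              estimate = y, se = se))
    oracle <- brute_dl(y, se)
    for (f in c("estimate", "se", "ci_lo", "ci_hi", "Q", "tau2", "i2"))
      expect_equal(res[[f]], oracle[[f]], tolerance = 1e-10, label = f)
  }
})

test_that("DL agrees with metafor's DerSimonian-Laird fit", {
  set.seed(7)
  y <- rnorm(8, -1.3, 0.6)
  se <- runif(8, 0.1, 0.5)
  res <- dl_pool(data.frame(study_id = paste0("s", 1:8),
                            scale = "logit_prevalence",
                            estimate = y, se = se))
  m <- metafor::rma(yi = y, sei = se, method = "DL")
  expect_equal(res$estimate, as.numeric(m$beta), tolerance = 1e-10)
  expect_equal(res$se, m$se, tolerance = 1e-10)
  expect_equal(res$tau2, m$tau2, tolerance = 1e-10)
  expect_equal(res$Q, m$QE, tolerance = 1e-10)
  expect_equal(res$i2, m$I2, tolerance = 1e-8)
})

test_that("back-transform inverts the logit scale and preserves bound order", {
  res <- dl_pool(data.frame(study_id = "s", scale = "logit_prevalence",
                            estimate = 0, se = 0.3537))
  res <- back_transform(res)
  expect_equal(res$estimate_bt, 0.5)
  expect_equal(expit(-1.3863), 0.20, tolerance = 1e-4)
  expect_true(res$ci_lo_bt < res$estimate_bt &&
                res$estimate_bt < res$ci_hi_bt)

  smc <- back_transform(dl_pool(data.frame(study_id = "s", scale = "smc",
                                           estimate = 0.44, se = 0.1)))
  expect_equal(smc$estimate_bt, smc$estimate)  # identity on the d scale
})

test_that("homogeneous corpora pool to the common proportion exactly", {
  corpus <- homogeneous_corpus(5, months = c(1, 3), x = 12, n = 100)
  res <- pool_point_prevalence(corpus, 1)
  expect_equal(res$estimate_bt, 0.12, tolerance = 1e-12)
  expect_equal(res$i2, 0)

  # every study n1 = 20 -> t2 = 10: pooled back-transformed reduction 0.5
  corpus <- homogeneous_corpus(4, months = c(1, 6), x = c(20, 10), n = 100)
  res <- pool_reduction(corpus, c(1, 6))
  expect_equal(res$estimate_bt, 0.5, tolerance = 1e-12)

  # identical d = 0.44 studies pool to d = 0.44 with I2 = 0
  corpus <- homogeneous_corpus(4, months = c(1, 6), x = c(20, 10), n = 100,
                               sympt_mean = c(30, 25.6), sympt_sd = 10)
  res <- pool_symptom_change(corpus, c(1, 6), r_assumed = 0.6)
  expect_equal(res$estimate, 0.44, tolerance = 1e-12)
  expect_equal(res$i2, 0)
})

test_that("a month with no data errors; mixed scales refuse to pool", {
  corpus <- homogeneous_corpus(3, months = c(1, 3), x = 12, n = 100)
  expect_error(pool_point_prevalence(corpus, 12), "12")
  mixed <- data.frame(study_id = c("a", "b"),
                      scale = c("smc", "logit_prevalence"),
                      estimate = c(0, 0), se = c(0.1, 0.1))
  expect_error(dl_pool(mixed), "mixed scales")
})

test_that("pooled estimate stays in the convex hull of study estimates", {
  set.seed(99)
  for (case in 1:10) {
    k <- sample(2:10, 1)
    y <- rnorm(k)
    se <- runif(k, 0.05, 1)
    res <- dl_pool(data.frame(study_id = paste0("s", 1:k), scale = "smc",
                              estimate = y, se = se))
    expect_true(res$estimate >= min(y) - 1e-12 &&
                  res$estimate <= max(y) + 1e-12)
  }
})

test_that("I2 is invariant to a common rescaling of the effect scale", {
  # rescaling estimates and SEs together (a change of units) leaves Q,
  # and hence I2, unchanged
  set.seed(3)
  y <- rnorm(6)
  se <- runif(6, 0.1, 0.4)
  base <- dl_pool(data.frame(study_id = paste0("s", 1:6), scale = "smc",
                             estimate = y, se = se))
  scaled <- dl_pool(data.frame(study_id = paste0("s", 1:6), scale = "smc",
                               estimate = 3 * y, se = 3 * se))
  expect_equal(base$i2, scaled$i2, tolerance = 1e-10)
  expect_equal(base$Q, scaled$Q, tolerance = 1e-10)
})

test_that("when tau2 truncates to zero DL equals the fixed-effect estimate", {
  y <- c(0.10, 0.11, 0.09, 0.105)
  se <- c(0.3, 0.1, 0.2, 0.25)
  res <- dl_pool(data.frame(study_id = paste0("s", 1:4), scale = "smc",
                            estimate = y, se = se))
  expect_equal(res$tau2, 0)
  w <- 1 / se^2
  expect_equal(res$estimate, sum(w * y) / sum(w), tolerance = 1e-12)
})

test_that("the correlation sweep changes only CI width, monotonically", {
  # exact in the equal-weight regime (studies of equal size, tau2 = 0)
  corpus <- homogeneous_corpus(6, months = c(1, 6), x = c(20, 10),
                               n = 100, sympt_mean = c(30, 25.6),
                               sympt_sd = 10)
  sweep <- pool_symptom_change(corpus, c(1, 6))
  ests <- sapply(sweep, `[[`, "estimate")
  expect_true(max(ests) - min(ests) < 1e-12)
  widths <- sapply(sweep, function(r) r$ci_hi - r$ci_lo)
  expect_true(all(diff(widths) < 0))  # increasing r narrows the CI

  # on unequal-size corpora the r grid reweights studies, so the pooled
  # estimate may drift a little; it must stay close to r-invariant
  corpus <- simulate_corpus(sim_truth(k = 6, seed = 77))$corpus
  sweep <- pool_symptom_change(corpus, c(1, 6))
  ests <- sapply(sweep, `[[`, "estimate")
  expect_lt(max(ests) - min(ests), 0.06)
})

test_that("forest data back-transforms per-study rows and weights sum to 100", {
  corpus <- homogeneous_corpus(4, months = c(1, 3), x = c(12, 9), n = 100)
  res <- pool_point_prevalence(corpus, 1)
  fd <- forest_data(res)
  expect_equal(nrow(fd), 4)
  expect_equal(sum(fd$re_weight_pct), 100)
  expect_equal(fd$estimate_bt, rep(0.12, 4), tolerance = 1e-12)
  expect_true(all(fd$ci_lo_bt < fd$estimate_bt))
})
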