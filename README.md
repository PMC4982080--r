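# longimeta

Random-effects meta-analysis of the **course of PTSD in trauma-exposed
children and adolescents** over the first year after a trauma. The
package is for researchers synthesizing longitudinal cohorts in which the
same children were assessed for PTSD (diagnostic status and/or symptom
severity) at several posttrauma waves, nominally 1, 3, 6 and 12 months.
It answers the questions behind "watchful waiting": how common is PTSD in
the acute phase, how much natural recovery happens between which time
points, and when does the course plateau?

## What it computes

Per study and assessment frame, three effect sizes:

* **Logit point prevalence** — `logit(x/n)` with binomial SE
  `sqrt(1/x + 1/(n−x))`, back-transformed to a proportion after pooling.
* **Relative prevalence reduction** — the fraction of initial cases who
  lost the diagnosis, `R = 1 − n₂/n₁`, logit-transformed; `R = 0` is
  replaced by 0.01 (1%) to allow the transform; the SE uses the case
  count at the earlier wave, `sqrt(1/(n₁R) + 1/(n₁(1−R)))`. Attrition is
  handled by imputing dropouts at the earlier wave's case rate, bounded
  by all-dropouts-are-cases / no-dropouts-are-cases sensitivity variants.
* **Standardized mean symptom change** — `d = (m₁ − m₂)/s_pooled` with
  variance `2(1−r)/n + d²/(2n)`, swept over assumed pre–post
  correlations `r ∈ {0.2, 0.4, 0.6, 0.8}`.

Effects are pooled with the **DerSimonian–Laird** random-effects
estimator (Q, τ², I², normal-theory 95% CIs), moderators are screened
with univariable **REML meta-regression with Knapp–Hartung** inference,
and small-study effects are probed with funnel data plus the Egger
regression. A child-level simulator generates multi-study corpora with
known truth (acute prevalence 21%, net recovery 17% over months 1–3 and
53% over months 1–6, symptom decline d = 0.44 over months 1–6,
between-study heterogeneity in the I² > 85% regime, 15% MCAR dropout per
follow-up wave) for parameter-recovery and calibration experiments.

## Worked example

```r
library(longimeta)

truth  <- sim_truth(k = 18, seed = 42)   # calibrated generating values
corpus <- simulate_corpus(truth)$corpus
corpus
#> <ptsd_corpus> 18 studies (synthetic), 72 study-waves

pool_point_prevalence(corpus, 1)
#> <pooled_result> prevalence_month1 (k = 18)
#>   logit_prevalence scale: -1.4243 [-1.7656, -1.0829]
#>   back-transformed: 0.194 [0.146, 0.253]
#>   Q = 367.102 (df = 17), tau2 = 0.5074, I2 = 95.4%

pool_reduction(corpus, c(1, 6), variant = "mcar")
#> <pooled_result> reduction_1-6_mcar (k = 18)
#>   logit_reduction scale: -0.5013 [-0.7242, -0.2783]
#>   back-transformed: 0.377 [0.326, 0.431]
#>   Q = 42.795 (df = 17), tau2 = 0.1200, I2 = 60.3%

sensitivity_suite(corpus, frames = list(c(1, 6)))$reduction
#>   frame           variant  k estimate_bt ci_lo_bt ci_hi_bt significant robust
#> 1   1-6              mcar 18      0.3772  0.32647   0.4309        TRUE  FALSE
#> 2   1-6 all_dropouts_ptsd 18      0.0141  0.00599   0.0328       FALSE  FALSE
#> 3   1-6  no_dropouts_ptsd 18      0.6559  0.60281   0.7054        TRUE  FALSE
```

Reading the numbers: the pooled acute prevalence (19.4%, CI 14.6–25.3%)
recovers the generating 21% up to between-study noise, with the high I²
the generator is calibrated to. The pooled 1→6-month reduction under the
primary imputation (37.7%) sits *below* the generating 53% by roughly
the completer fraction — the imputation rule deliberately holds dropouts
at their baseline case rate, so it is conservative when dropouts in fact
keep recovering — and is bracketed by the two sensitivity bounds (1.4%
and 65.6%), whose disagreement is exactly why the suite flags the frame
as non-robust at this dropout level. The methods vignette
(`vignettes/child-ptsd-course.Rmd`) derives this attenuation and the
rest of the design.

`run_full_analysis(corpus, out_dir = "results")` executes the whole
grid — 4 point-prevalence months, 4 change frames × 3 attrition
variants, 4 frames × 4 correlations — plus moderator screens and funnel
diagnostics, writing CSV tables, a log of every continuity/clamp event,
and a manifest.

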