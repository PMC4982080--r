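---
title: "Modelling the course of child PTSD: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the course of child PTSD: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longimeta)
```

## The scientific problem

Clinical guidelines for posttraumatic stress disorder (PTSD) in children
and adolescents assume an acute elevation of symptoms followed by
substantial natural recovery in the first months after a trauma — the
rationale for "watchful waiting" before intervening. Quantifying that
course requires pooling longitudinal cohorts that assessed the same
children repeatedly over the first posttrauma year. `longimeta`
implements that pooling pipeline: study-level effect sizes for point
prevalence, relative prevalence reduction, and standardized mean symptom
change; DerSimonian–Laird random-effects synthesis with heterogeneity
statistics; univariable meta-regression over prespecified moderators; and
funnel-based small-study diagnostics. A child-level simulator with known
generating values makes every stage testable without access to the
original cohort data.

## Data model

A corpus is a set of study records, each combining study-level moderators
(mean age; percent boys; measurement by self-report cut-off vs diagnostic
interview, coded 0/1; whether the acute assessment fell at < 4 weeks or
4–6 weeks posttrauma, coded 0/1; informant) with per-wave outcomes: the
number assessed, the number meeting PTSD criteria, and/or the mean and SD
of a symptom scale. Waves are harmonized to nominal months 1, 3, 6 and 12
using tolerance windows of 2–6, 9–17, 22–30 and 48–57 weeks since trauma
(closed intervals — chosen so that reported timings such as "6 weeks" for
an acute assessment and "30 weeks" for a 6-month one land inside their
windows; the four windows are disjoint, so assignment is deterministic,
and timings between windows are simply not harmonizable). The bundled
`table1_metadata()` table carries the metadata of the 28 source cohorts
(N = 24–548, children aged 5–18) to which the simulator is calibrated;
per-wave outcome counts are user-supplied or simulated.

Two data-handling conventions matter. When a follow-up wave reports no
`n_assessed`, it defaults to the baseline N with a warning — the fallback
used when attrition is unreported. Parent-report studies are accepted but
flagged, since parents tend to under-report child symptoms; child report
is preferred when both exist.

## Effect sizes

**Point prevalence.** For `x` cases among `n` assessed, the working
effect is the log-odds `logit(x/n)` with the binomial delta-method
standard error `sqrt(1/x + 1/(n − x))`. Boundary counts (`x = 0` or
`x = n`) receive the standard half-count correction on both cells
(`x' = x + 0.5`, `n' = n + 1`), recorded in the effect's flags. Pooled
values are back-transformed to proportions for interpretation.

**Relative prevalence reduction.** The course statistic is the fraction
of initial cases who lost the diagnosis between two waves,
`R = 1 − n₂/n₁` where `n₁`, `n₂` are case counts at the earlier and later
wave. This assumes later cases are a subset of earlier cases — reasonable
because delayed-onset PTSD affects only a small percentage of children
(about 2%). When the count did not change, `R = 0` is replaced by 0.01
(1%) to allow the logit transformation; the same floor extends to
increases, and complete recovery is capped at 0.99, all flagged and
logged. Because the statistic concerns only the subset with PTSD at the
earlier wave, the SE uses the case count, not the whole sample:
`se = sqrt(1/(n₁R) + 1/(n₁(1−R)))`.

**Attrition imputation.** With `N` assessed at the earlier wave but only
`m` completers at the later one (`c` of them cases), the later case total
is imputed under three assumptions: the primary rule gives dropouts the
earlier wave's case proportion (`c + (N − m)·n₁/N`, kept fractional), and
the sensitivity bounds count all dropouts as cases or none. By
construction the resulting reductions are ordered
`R(all) ≤ R(primary) ≤ R(none)` study-wise and pooled, and all three
coincide when there is no attrition.

One property of the primary rule deserves emphasis: it deliberately holds
dropouts at their *baseline* case rate. If the children lost to follow-up
in fact keep recovering like completers, the estimated reduction is
attenuated by the completer fraction — with dropout rate δ per interval,
the estimand is approximately `R·(1 − δ)` per interval rather than `R`.
The rule is therefore conservative (it understates recovery under benign
dropout), bounded by the two sensitivity variants. The package's
recovery experiments verify both faces of this: exact unbiasedness on
attrition-free corpora, and the `(1 − δ)` attenuation under simulated
MCAR dropout.

**Standardized mean change (SMC).** For symptom means `m₁`, `m₂` with
SDs `sd₁`, `sd₂` over the same cohort,
`d = (m₁ − m₂)/s_p` with `s_p = sqrt((sd₁² + sd₂²)/2)` (the unweighted
two-wave pooling is appropriate because both waves cover the same
cohort); positive `d` is symptom decline. The sampling variance of a
within-cohort change depends on the pre–post correlation `r`, which the
source studies almost never report:
`var(d) = 2(1 − r)/n + d²/(2n)`. The analysis is therefore run over the
grid `r ∈ {0.2, 0.4, 0.6, 0.8}` and reported as a sensitivity sweep. The
per-study point estimate is exactly invariant to `r` and its variance
strictly decreasing in `r`. The *pooled* estimate is exactly invariant
only when studies carry equal weights: on corpora with very unequal
sample sizes the `r` grid reweights studies and the pooled value can
drift by a few hundredths of a `d` unit — which is precisely why the
sweep is worth reporting rather than a single `r`.

## Random-effects pooling

Pooling uses the DerSimonian–Laird method-of-moments estimator, matching
the standard Stata `metan` behaviour: fixed weights `wᵢ = 1/seᵢ²`,
Cochran's `Q`, `τ² = max(0, (Q − df)/C)` with
`C = Σw − Σw²/Σw`, random-effects weights `1/(seᵢ² + τ²)`, a
normal-theory 95% CI, and `I² = max(0, (Q − df)/Q)·100`. A single study
pools to itself with `τ² = 0` and `I²` not applicable. No Knapp–Hartung
adjustment is applied at the pooling stage (that is the named routine's
default); the adjustment is applied in meta-regression, below, where
small-sample inference on a slope is the point.

Two properties worth stating precisely. `I²` is invariant to a change of
units (rescaling estimates and SEs together leaves `Q` unchanged); it is
*not* invariant to rescaling SEs alone, which changes the
signal-to-noise ratio `I²` measures. And DL normal-theory CIs are known
to undercover at small-to-moderate `k` when heterogeneity is high: in
this package's own calibration experiments (k = 15, 1000 replicates)
coverage is ≈ 96% under homogeneity but ≈ 90–92% when `τ` is set so
`I² ≈ 90%` — the regime the source corpus occupies. That undercoverage
is a documented limitation of the estimator this pipeline faithfully
reproduces, not a defect of the implementation; it is the reason later
methodological work recommends Hartung–Knapp-type intervals for pooling
as well.

## Meta-regression and small-study diagnostics

Univariable mixed-effects meta-regressions relate effects to one
moderator at a time (study sets per analysis are small, 4–18). The
residual `τ²` is estimated by REML (numerically profiled), and inference
on the slope uses the Knapp–Hartung adjustment — the WLS covariance is
rescaled by the standardized residual sum of squares over `k − 2`, with a
t-reference on `k − 2` df. The adjustment is what keeps the type-I error
near 5% at `k ≈ 10`; the package's null-moderator simulation verifies
this calibration. Moderator applicability follows the prespecified rules:
measurement type applies to prevalence-based analyses only, initial
prevalence to change analyses only, and acute-assessment timing only to
analyses involving the 1-month wave.

Funnel diagnostics emit the (estimate, SE) pairs and the Egger
regression of the standardized effect on precision, a numeric supplement
to visual funnel inspection. Note the sign convention: prevalence effects
sit on the negative half of the logit scale, so *missing small
high-prevalence studies* leave the remaining small studies' standardized
effects below the line the large studies anchor, i.e. a negative Egger
intercept.

## The simulator: what it emulates and what it does not

Studies are simulated at the level of individual children, because the
analysis' assumptions (monotone diagnosis loss, rare delayed onset,
attrition, correlated pre–post symptom scores) are assumptions about
children, not about study summaries.

* Study size is uniform on 24–548, the range of the source cohorts;
  moderators are drawn from realistic ranges (mean age 9–17 years,
  40–80% boys, 25% diagnostic-interview studies).
* The study's acute (1-month) prevalence is
  `expit(logit(0.21) + moderator terms + N(0, τ))` with `τ = 0.6`,
  chosen so the pooled acute analysis sits in the `I² > 85%` regime the
  source corpus reports while centring the logit-scale pooling target at
  21%.
* Children recover between consecutive waves with a probability
  calibrated, against the study's realized case count, so the *net*
  expected relative reduction per interval hits the target exactly
  despite delayed-onset inflow (a non-case newly meets criteria with
  probability 0.02 per transition). Net reductions then compose
  multiplicatively across intervals. A study-level normal effect on the
  logit of the net reduction (`τ_red = 0.5`) makes some cohorts
  fast-recovering and others stable, giving the substantial heterogeneity
  the reduction analyses show.
* The published per-frame estimates come from *different study subsets*
  and are mutually inconsistent as a single cohort chain (a 17%
  reduction over months 1–3 and 53% over months 1–6 imply 43% over
  months 3–6, not the separately published 32%; the published SMC values
  0.37 + 0.27 ≠ 0.44 likewise). The generator therefore calibrates its
  consecutive-interval chain to the 1–3 month (17%) and 1–6 month (53%)
  values and lets the other frames follow from composition. Recovery
  experiments target the frames the chain is calibrated to.
* Symptom scores are equicorrelated normal within child (shared-factor
  construction, `r_true = 0.6`), mean 30 and SD 12 in arbitrary
  instrument units (standardization absorbs the scale), with wave means
  declining so that `d = 0.44` between months 1 and 6.
* Dropout is monotone, 15% per follow-up wave, missing completely at
  random by default; an informative-dropout switch roughly doubles the
  dropout probability of current cases, for stress-testing the
  imputation variants.
* Seeding: one master seed with deterministic per-study (and
  per-replicate) substreams, so corpora are reproducible byte-for-byte
  while studies remain independently variable.

Features of real data the simulator does **not** emulate, and which
passing tests therefore say nothing about: trauma-type-specific
trajectory shapes (the source corpus was dominated by accidental injury
and could not analyse trauma type), instrument-specific scoring and
harmonization across symptom scales, non-normal between-study effect
distributions, within-study clustering (siblings, sites), and
selective publication. Symptom scores are generated independently of
diagnostic status; the two outcome streams agree in their means but are
not coupled child-by-child.

## Numerical and design choices

* Continuity handling: 0.5/both-cells for boundary prevalence counts;
  the 1% substitution for zero (or negative) change on the reduction
  scale, 99% cap for complete recovery. Every such event is flagged on
  the effect and logged by the pipeline runner — these are the analysis'
  most fragile steps and should be auditable.
* Fractional imputed case totals are kept unrounded; rounding direction
  is not well defined and discards information.
* Wave windows are closed intervals (see above); degenerate inputs
  (no eligible studies for a frame, `k` below the configured minimum,
  constant moderators) are skipped with reasons rather than failing the
  run, mirroring how the source analysis dropped its k = 2 frame.
* REML is profiled on `[0, max(10·var(y), 0.001)]` with tolerance 1e-9;
  the boundary `τ² = 0` is compared explicitly.
* The problem sizes used by the test suite and the acceptance script
  (400–1000 Monte-Carlo replicates, corpora of 6–18 studies) give
  Monte-Carlo standard errors comfortably below the asserted tolerances
  (e.g. ±0.001–0.005 on recovered proportions at 400–500 replicates).

## Worked example

```{r example}
truth <- sim_truth(k = 18, seed = 42)
corpus <- simulate_corpus(truth)$corpus
corpus

pool_point_prevalence(corpus, 1)

pool_reduction(corpus, c(1, 6), variant = "mcar")

sens <- sensitivity_suite(corpus, frames = list(c(1, 6)))
sens$reduction
```

The acute pooled prevalence recovers the generating 21% up to
between-study noise; the reduction under the primary imputation sits
below the generating 53% by roughly the completer fraction (15% dropout
per interval, two intervals), bracketed by the all-dropouts and
no-dropouts bounds — the attenuation discussed above, visible in a
single run.

## Limitations

Beyond the simulator's scope notes above: the pipeline reproduces a
particular, historically situated analysis style (DL pooling with
normal-theory CIs, univariable moderator screens without multiplicity
control, visual-plus-Egger funnel inspection). It is faithful to that
style rather than to current best practice; users wanting
Hartung–Knapp pooled intervals, multivariate or dose-response
meta-regression, or selection-model bias adjustment should treat this
package as the reproduction baseline, not the final word.
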