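---
title: "Decomposing mortality inequalities on the additive hazard scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing mortality inequalities on the additive hazard scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the model

Mortality differs between racial/ethnic groups in the US. One candidate
explanation is lifestyle: groups differ in their distributions of alcohol
use, smoking, body mass and physical activity (*differential exposure*), and
the same lifestyle category may carry a different mortality penalty in
different groups (*differential vulnerability*). `medhaz` implements a
causal mediation analysis that separates these two mechanisms, mediator by
mediator, on the **additive hazard scale**, where effects are extra deaths
per person-year and additive interactions are directly interpretable for
public health.

The outcome model is a Lin–Ying-type additive hazards model on the **age
timescale** with delayed entry: a subject surveyed at age $a_0$ enters the
risk set at $a_0$ and leaves at death or administrative censoring (end of
2015). The marginal structural (natural effects) model is

$$\lambda(a \mid R, R^*_1,\dots,R^*_4) \;=\; \lambda_0(a) + \theta_1 R +
\sum_{k=1}^{4}\theta_{2k} R^*_k + \sum_{k=1}^{4}\theta_{3k}\, R\, R^*_k +
\eta' C,$$

where $R$ is the observed exposure (contrast group vs white), $R^*_k$ an
*auxiliary* exposure steering mediator $k$, and $C$ the covariates
(education, marriage, survey year); age never appears as a regressor because
it is the timescale. The estimator follows the natural-effects data-expansion
template: each subject is replicated over all $L^4$ joint assignments of
$(R^*_1,\dots,R^*_4)$ and the replicate with assignment $r^*$ receives the
weight

$$W = \prod_k \frac{\hat P_k(M_k \mid R = r^*_k, C)}
                   {\hat P_k(M_k \mid R = R_{\text{obs}}, C)},$$

with $\hat P_k$ a baseline-category multinomial logit fitted per sex
stratum. The weighted fit identifies $\theta_1$ as the (pure) direct effect,
$\theta_{2k}$ as differential exposure through mediator $k$ (the pure
indirect effect), and $\theta_{3k}$ as differential vulnerability (the
mediated interaction). Totals and the net indirect effect are defined as the
sums of fitted components, so the decomposition is additive *by
construction*, mirroring how such tables are printed. All results are
scaled to deaths per 10,000 person-years only at reporting.

Mediators are assumed not to affect one another (they enter as parallel
pathways), there must be no unmeasured confounding of the
exposure–outcome, exposure–mediator and mediator–outcome relations, and
every mediator level needs positive modeled probability under every
counterfactual exposure (positivity).

## Harmonization rules

Raw lifestyle reports are categorized with the conventional cutpoints:
grams of pure alcohol per day from drinking frequency and quantity at 14 g
per drink over a 365-day year, classed by sex-specific half-open intervals
(men $(0,40], (40,60], >60$; women $(0,20], (20,40], >40$ g/day) with
never/former drinkers separated by the lifetime 12-drinks criterion;
smoking as never/former/someday/everyday; BMI as right-open WHO classes
($<18.5$, $[18.5,25)$, $[25,30)$, $\ge 30$); physical activity in
moderate-equivalent minutes per week (vigorous counts double) as sedentary
(exactly 0), somewhat active $(0,150)$ and active ($\ge 150$). Reference
categories are category I drinking, never smoking, normal weight, and
active. The right-open BMI convention closes the gap left by printed
ranges like "18.5–24.99"; "sedentary" is exactly zero minutes so the
somewhat-active class opens strictly above 0.

## The synthetic cohort and its ground truth

Because the linked survey–mortality microdata cannot ship with a package,
`cohort_params()`/`generate_cohort()` define an NHIS-like cohort with known
causal structure: race (white/black, optionally hispanic) →
race-conditional covariates (truncated-normal age on [18, 85], education,
marriage, survey year 1997–2014) → mediators from baseline-category logits
→ survival from the additive hazard
$\lambda_0^{sex}(a) + \beta_R + \sum_k(\gamma_k[m_k] + \delta_{R,k}[m_k]) +
\eta'C$, with piecewise-constant Gompertz-like baselines, administrative
censoring at entry $+ (2016 - \text{survey year})$, and a hard cap at age
100. Default intercepts and race coefficients are loosely calibrated to
published unweighted NHIS prevalences (for instance ~20% everyday smokers
and ~1% underweight among white men) — they are illustrative conditions,
not estimates. Negative assembled rates are clipped at zero; generation
aborts if clipping exceeds 1% of person-time (defaults clip essentially
nothing).

`true_decomposition()` computes what the estimator targets. Writing
$g_k(r) = \sum_m \gamma_k[m] P(M_k = m \mid R = r, C)$ and
$D_k(r) = \sum_m \delta_k[m] P(M_k = m \mid R = r, C)$, the components are

* differential exposure: $E_C[g_k(r) - g_k(0)]$,
* differential vulnerability (mediated interaction): $E_C[D_k(r) - D_k(0)]$,
* direct (pure direct effect): $\beta_r + \sum_k E_C[D_k(0)]$,

averaged over the covariate law of the two-group analytic sample for the
given sex. This is the partition the MSM coefficients converge to; defining
the direct effect as $\beta_r$ alone and vulnerability as $E_C[D_k(r)]$
would sum to the same total but would not match what any Lange-style fit
estimates whenever $D_k(0) \ne 0$. A Monte-Carlo mode draws mediators
instead of using their probabilities and serves as a self-consistency
oracle. Under the additive generating hazard every component is invariant
to $\lambda_0$, which the tests exploit.

Two caveats the generator makes visible: the marginalization population for
natural effects had to be fixed somewhere (we use the two-group analytic
sample, matching the estimator); and the constant-coefficient MSM is a
projection — when $g_k(r, C)$ varies with covariates, the fitted constant
is a risk-set-weighted average of covariate-specific contrasts rather than
the baseline average. Default mediator laws keep covariate dependence
modest, so the two agree well within sampling error at the sizes used. The
generator also does not emulate complex survey design, time-varying
lifestyle, or mediator–mediator dependence, so passing tests speak to the
estimator under the stated assumptions, not to robustness against their
violation in real data.

## Numerical and design choices

* **Estimating equation, exactly.** The Lin–Ying equation is evaluated by
  decomposing integrals over the segments between consecutive distinct
  entry/exit ages (no event-time grid approximation). Risk intervals are
  half-open $(entry, exit]$; a subject entering exactly at an event age is
  not yet at risk (events-first); exact ties among event ages aggregate; no
  age jitter is applied, so fits are deterministic. A brute-force
  enumerator of the same equation (independent loops, $\le 50$ rows) is the
  in-package oracle, and the two agree to $10^{-10}$ on random instances.
* **Constant coefficients.** The single-number-per-effect reporting format
  forces time-invariant coefficients with a nonparametric baseline; the
  baseline estimator reduces to Nelson–Aalen at $\hat\beta = 0$. Fitted
  hazards may go negative (additive models do that); a diagnostic reports
  the person-time fraction affected rather than constraining the fit.
* **Standard errors.** Cluster-sandwich variances (martingale-increment
  scores summed within subject across replicates) give fast intervals; the
  primary intervals are subject-level nonparametric bootstrap percentiles
  because the weights are estimated. The whole pipeline — mediator fits,
  expansion, weights, truncation, MSM — reruns per replicate, implemented
  as multiplicity weights so replicated subjects are never materialized.
* **Weights.** Unstabilized, as in the natural-effects template (an optional
  within-pattern stabilization is provided); truncated by default at the
  99.5th percentile per stratum for variance control, with the affected
  count and mass always recorded. Identity replicates have weight exactly
  1 by construction, an exactness the tests assert literally.
* **Rare cells and the bootstrap.** The user-facing mediator fit refuses a
  mediator level unobserved in some race group (weights would rest on pure
  extrapolation) — but a bootstrap *resample* of an identified fit
  routinely loses a ~1% cell at realistic sizes. Replicate fits therefore
  skip the cell-occupancy check and rely on the smooth logit (with a tiny
  ridge fallback, decay $10^{-6}$, on separation only, always flagged).
  Replicates can still fail; more than 10% failures abort with a log.
* **Exposure contrasts.** Contrasts are fitted pairwise (reference + one
  group, 16-fold expansion) by default; a joint 3-level mode (81-fold)
  with the full set of race-by-auxiliary products is available.
* **Determinism.** One master seed drives named substreams (generator,
  bootstrap per stratum and replicate, truth, studies), so every run is
  exactly reproducible.

## Validation study sizes

The shipped tests validate, in increasing depth: categorization boundary
arithmetic; generator distributional law (KS test against the censored
exponential at a constant hazard); mediator-model parameter recovery
(n = 40,000) and the score-equation identity (tolerance $10^{-6}$);
exact weight identities; solver-vs-oracle agreement ($10^{-10}$, 100 random
instances); full-pipeline recovery of every closed-form component within
3 combined SEs at n = 50,000; null calibration of differential-exposure
intervals (cohorts of 5,000, 40 replications, B = 60 bootstrap draws,
pooled coverage of zero $\ge$ 0.90); and bootstrap coverage of all true
components (same sizes, pooled coverage within [0.90, 0.99]). The pooled
(across-component) coverage summaries reflect the replication counts a
single-CPU test run can afford; per-component banding stabilizes only
around 200+ replications. `scripts/acceptance.R` reruns the same suite of
quantities from scratch at a user-supplied seed.

## Known limitations

Ordered or causally dependent mediators, time-varying exposures and
mediators, survey design features (weights, strata, clusters), imputation,
and cause-specific mortality are out of scope. The published reference
table bundled for arithmetic checks cannot be reproduced from the synthetic
generator — its microdata are not public — and the package makes no attempt
to match its values, only its structure and identities.
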