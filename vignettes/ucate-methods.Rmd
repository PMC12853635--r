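---
title: "Estimating individual-specific effects in an N-of-1 abstinence trial"
author: "ucate package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating individual-specific effects in an N-of-1 abstinence trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ucate)
```

## The problem

An N-of-1 trial is a within-person crossover study: a single participant
alternates between treatment and comparator periods while outcomes are
measured repeatedly. `ucate` analyzes one such trial: a participant who
joined a month-long alcohol-abstinence campaign recorded, every 8 hours
(at 00:00, 08:00 and 16:00) from 2023-12-06 to 2024-03-02, his mood (5-point
Likert scale, −2..2), the alcohol units consumed in the preceding 8 hours,
and whether a social interaction occurred — 264 measurement points, 93 of
them attributed to the January abstinence period.

The estimand is the *U-CATE*: the average treatment effect conditional on
the participant's individual-specific state `U` at trial start. At each
measurement time it contrasts the expected mood under the static strategy
*always abstain* with the expected mood under *always drink as usual*,
conditional on `U` (implicitly, by design: every observation is conditioned
on it) and on the fixed calendar.

Naive before/after comparisons are confounded here: working-day structure
and social contact drive both drinking and mood, drinking and mood feed
back on each other across 8-hour lags, and alcohol is the full mediator of
the abstinence intervention. The package therefore implements a
g-computation (g-formula) approach over an explicit causal model.

## The assumed data-generating process

Time runs over the fixed grid $t = 0, 1, \dots, T-1$. Per point the model
uses: time of day $TD_t$ (reference 00:00), the non-working-day flag
$NW_t$, intervention status $I_t$, social interaction $S_t$, alcohol units
$AU_t$, and mood $Y_t$. Three conditional models, each assumed *stationary*
(the same conditional law at every $t$), generate the data given the
previous time point:

* **Social interaction** — logistic regression:
  $\text{logit}\, P(S_t = 1) = \beta_0 + \beta_1 AU_{t-1} + \beta_2 Y_{t-1}
  + \beta_3 NW_t + \beta_4 [TD_t{=}08] + \beta_5 [TD_t{=}16]$.

* **Alcohol units** — zero-inflated Poisson, fit on non-intervention points
  only. The zero component models the probability $\pi$ of a structural
  zero (a setting in which no drinking happens) on the logit scale; the
  count component models the Poisson mean $\lambda$ on the log scale. Both
  components use $Y_{t-1}$, $NW_t$, $TD_t$ and the *current* $S_t$:
  $P(AU_t = k) = \pi\,[k{=}0] + (1-\pi)\,\text{Pois}(k;\lambda)$.
  Under intervention, $AU_t \equiv 0$ deterministically.

* **Mood** — proportional-odds (cumulative logit) model over the five
  categories, parameterized as $P(Y_t \ge j) = \text{expit}(\alpha_j +
  x_t'\beta)$ with non-increasing cutpoints $\alpha_1 \ge \dots \ge
  \alpha_4$, so positive slopes mean better mood. Covariates: $AU_t$,
  $AU_{t-1}$, $Y_{t-1}$, $NW_t$, $TD_t$, $S_t$.

Identification rests on: an externally fixed treatment schedule; the
first time point treated as fixed (it only supplies lags); the
non-working-day and time-of-day sequences treated as fixed; conditional
stationarity of all three models; and deterministic zero consumption under
abstinence. A point belongs to the intervention period when its full
8-hour recall window lies inside the abstinence month, so the midnight
point of January 1 is a comparator point while the midnight point of
February 1 is an intervention point; the month contributes exactly
$3 \times 31 = 93$ points either way.

Lagged mood enters every model as a single numeric covariate (−2..2),
matching the single printed coefficient per model in the source fits.

## The estimator

`gcompute()` implements the g-computation Monte Carlo algorithm: for each
of `n_reps` (default 800) repetitions it simulates the whole trial forward
from the fixed first point twice — once under *always abstain* (alcohol
forced to zero; the alcohol model is never consulted) and once under
*never abstain* (alcohol always drawn from the fitted model, including
calendar-January times, which conditional stationarity licenses). The
per-time estimate is the mean over repetitions of the mood difference
between the arms, reported for every $t \ge 1$; the overall and
time-of-day aggregates are unweighted arithmetic means of those per-time
estimates.

By default the two arms share *common random numbers*: the same four
uniform blocks (social, alcohol-zero, alcohol-count, mood) per repetition
and time point drive both arms through inverse-CDF sampling. This leaves
each arm's marginal law untouched — hence the mean difference is unbiased —
while sharply reducing Monte Carlo variance; `coupled = FALSE` restores
independent arms. A useful corollary: if every alcohol pathway into mood
and social interaction is zero, the coupled arms coincide path by path and
the estimate is exactly zero.

`parametric_bootstrap()` quantifies estimation uncertainty as in the source
analysis: simulate `n_boot` (default 500) complete trials from the fitted
models under the observed treatment assignment and the observed first
point; refit all three models on each; rerun the g-computation; use the
across-replicate standard deviation (sample, $n-1$ denominator) at each
time point as the standard error and form 95% intervals by normal
approximation around the point estimates. Aggregate standard errors come
from the bootstrap distribution of the replicate-level aggregate mean.
Replicate $b$ runs on a deterministic sub-seed of (master seed, $b$), so
results are reproducible and invariant to replicate order.

Because the published zero-inflation component is quasi-separated (slopes
of magnitude 13–25), occasional unstable refits are expected. The policy:
a failed or non-converged refit is retried once with a small ridge penalty
on the slopes (`refit_penalty`, default 0.01); if it still fails the
replicate is dropped and logged in the diagnostics; if more than 20% of
replicates fail the bootstrap aborts. Reported effective sample sizes use
only successful replicates.

## The synthetic-data generator

The original dataset is private, so `default_config()` defines a generator
whose slopes are exactly the published point estimates for all three
models. Quantities the source does not print were chosen once and frozen:

* **Intercepts/cutpoints** — calibrated by simulation against the published
  descriptives of the non-intervention period (social interaction 27.5%,
  mean alcohol 1.01 units, mean mood 0.47): social intercept −0.55,
  zero-inflation intercept 0.35, count intercept 0.12, mood cutpoints
  (3.70, 2.55, 0.15, −3.40). Achieved marginals: social ≈ 26.7%, alcohol
  ≈ 1.00 (SD 2.06), mood ≈ 0.50 (SD 0.88). Exact matching is impossible
  (the true intercepts are unpublished) and not attempted.
* **Non-working days** — weekends plus Berlin public holidays plus a
  configurable vacation list; the default list (Dec 27–29, Jan 2,
  Feb 12–13) reproduces the published non-working counts exactly
  (73/171 and 29/93).
* **First time point** — fixed at the neutral center (no social contact,
  zero alcohol, mood 0); the source fixes the first point but does not
  print it, and any in-range value is valid.
* **Tamed variant** — `default_config(tamed = TRUE)` clips the
  zero-component slopes to ±3. The printed values (13.06, 25.36, −24.18)
  encode quasi-complete separation; simulating from them is fine, but
  maximum likelihood on such data sits on the boundary, so
  parameter-recovery work uses the tamed variant.

The generator emulates the conditional-distribution structure and calendar
of the real trial. It does **not** emulate early/late reporting, sickness
episodes, behavior change after the campaign, or measurement error — so
passing recovery and calibration tests demonstrates internal consistency
of estimator and model, not robustness to those real-data features.
`predictive_check()` (simulation envelopes for summary statistics, in the
spirit of a visual predictive check against 100 simulated series) is the
tool for judging model adequacy on real data.

## Numerical choices

* Linear predictors are clipped to ±35 before `expit`/`exp`; quasi-separated
  coefficient sets then produce probabilities within 10⁻¹⁵ of 0/1 instead
  of overflowing.
* All randomness is inverse-CDF from pre-drawn uniforms, in four
  per-variable blocks per simulation (social, alcohol-zero, alcohol-count,
  mood). Adding a future variable would append a block rather than shift
  existing draws, and the blocks make arm coupling exact. The sequential
  inner loop is compiled (Rcpp); the uniforms are drawn on the R side so
  `set.seed` governs everything.
* The ZIP model is fit by direct maximum likelihood (BFGS with analytic
  gradient; SEs from the numerical Hessian). This keeps each refit in the
  ~10 ms range — the bootstrap-calibration experiment alone performs
  20,000 refits — and admits the ridge retry. The fit is cross-checked
  against an independent implementation in the test suite.
* The proportional-odds fit keeps the category set fixed at −2..2. If a
  bootstrap sample misses a boundary category, its cutpoints map to ±∞
  (probability zero) and a flag is raised instead of silently re-indexing
  categories, so effects stay on a stable scale. With exactly two observed
  categories the model is fit as the equivalent logistic regression.
* Quasi-separation is flagged (|coef| > 10 or SE > 50) but the unpenalized
  ML solution is kept by default, since separated fits can still predict
  well; the ridge penalty is opt-in (`ridge`) and used automatically only
  for bootstrap refit retries.

## Problem sizes used by the test suite

Parameter recovery refits on a 30,000-point simulated series (10,000 days,
all non-intervention), where the published slopes are recovered within a
few hundredths. The bootstrap-calibration experiment uses 200 simulated
20-day trials (60 points, 4-day abstinence block) with a tame, separation-
free coefficient set, 100 bootstrap replicates and 200 inner g-computation
repetitions per trial, against a truth computed once at 10⁵ repetitions;
these sizes keep the whole experiment in the ten-minute range on a single
CPU while leaving the binomial 99% acceptance band informative. The
enumeration oracle checks the estimator on a one-day grid by exact dynamic
programming over the joint state.

## Limitations

Everything rests on the assumed causal structure and on conditional
stationarity; neither is testable from one trajectory. Estimates are
individual-specific by construction and do not generalize beyond the
participant. The normal-approximation bootstrap interval can undercover
when refits sit near separation; the diagnostics table reports how many
replicates were ridged or dropped. The alcohol model is fit only on
non-intervention points, so strategies are evaluated under the assumption
that non-intervention drinking behavior extends to counterfactual January
drinking.
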