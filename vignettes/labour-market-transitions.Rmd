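---
title: "Modelling labour-market transitions as a discrete-time multi-state Markov chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling labour-market transitions as a discrete-time multi-state Markov chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labmarkov)
```

## The problem

Administrative registers record, for every resident and every calendar year,
earnings, compensated benefit days by social-insurance programme, income by
source, hospital inpatient days, and vital/migration events. From these one
can ask how people who are jobless at a baseline year move, over many years,
between joblessness, self-sufficiency (main income from work), and
health-related work incapacity — and how much of that movement is explained
by who they are (sex, age, education, country of birth), how ill they have
been (recent inpatient care), and what the national labour market looked
like at the time.

`labmarkov` implements that analysis end to end: a two-step classifier from
raw register variables to four mutually exclusive states, a person-period
panel builder over an unequally spaced follow-up design, a from-scratch
multinomial-logit maximum-likelihood estimator for first-order Markov
transition models, and a predictor that converts coefficients — fitted, or
injected from a published odds-ratio table — into stratified
transition-probability tables. Because the original registers are not
redistributable, the package ships a synthetic register generator with known
ground-truth dynamics; every stage is tested against it.

## States and classification

Each person-year is first assigned one of nine labour-market positions, then
collapsed to four states:

| State | Positions |
|---|---|
| Jobless | long-term registered unemployed (≥ 6 months compensated), social assistance, minimal income |
| Self-sufficient | employed above an earnings threshold, long-term parental leave, student allowance |
| Disabled | long-term sickness absence, disability pension |
| Censored | death, emigration, old-age pension (absorbing) |

The first step applies rule families in a fixed precedence: death >
emigration > benefit-day rule > income-share rule > employed > minimal
income. The benefit-day rule fires when the *sum* of compensated days across
the four programmes (unemployment, sickness, disability, parental) reaches
`long_term_days` (default 183, i.e. half of 366 — the sources specify only
"six months", so the day count is configurable); the year is then assigned
to the programme with the most days, ties broken disability > sickness >
unemployment > parental. The income-share rule fires when more than half
(`income_share_cut`, default 0.5) of disposable income comes from social
assistance, student allowance, or an old-age pension. Whether the original
analysis evaluated the employed-earnings rule before or after the share
rules cannot be determined from its description; we place the share rules
first so that welfare and pension statuses dominate earnings, which is
consistent with the published position table presenting "employed" as the
residual majority. Every decision is reported through a `triggered_rule`
column, and an independent rule-by-rule oracle in the test suite confirms
the precedence on fuzzed records.

Censoring is absorbing at the cohort level: once a person's year is
Censored, every later year is Censored, even if records reappear after
re-immigration. A record with transfer income but missing or non-positive
disposable income is an explicit error, never a silent zero-division.

## The panel and the models

States are measured at unequally spaced years (default 1995, 1997, 2001,
2005, 2008, 2010, indexed p = 0..5), chosen to bracket rising and falling
national unemployment. The study population is everyone Jobless at p = 0.
For each period p ≥ 1 with a non-Censored previous state, one person-period
row records the origin and outcome states plus covariates:

* sex, age group (20–25, 26–30, 31–35, 36–40 — the first group spans six
  years, exactly as in the published reference categories) and country of
  birth, all fixed at baseline;
* education (Lower / High school / Higher) at the *previous* period's year,
  so the covariate is genuinely time-varying and predates the outcome;
* inpatient-care days over the two calendar years before the outcome year,
  categorised 0 / ≤ median / > median, the median computed among panel rows
  with any care, separately per period. (Whether the original median was
  per-period or pooled is not stated; per-period is our choice and is
  recomputable from the panel, so shuffling row order can never change a
  category.) Years without records — e.g. after death — contribute zero
  days.

Three nested models are estimated with outcome state `State_p` and reference
outcome Jobless:

* Model 1: previous state only — a homogeneous first-order Markov chain;
* Model 2: + sex, age group, education at p−1, country of birth;
* Model 3: + inpatient-care category and period dummies.

Estimation is multinomial-logit maximum likelihood, written in the package
rather than delegated: the three non-reference equations (Self-sufficient,
Disabled, Censored, each versus Jobless) are maximised jointly so the four
predicted probabilities always sum to one. The optimiser is Newton–Raphson
with the analytic gradient and block Hessian, step-halving on any likelihood
decrease, convergence at gradient max-norm < 1e−8 (at most 100 iterations),
and an honest `converged` flag. Repeated rows per person are treated as
independent, which is exactly the conditional-independence content of the
first-order Markov assumption; standard errors are therefore model-based,
with no clustering adjustment. Rank-deficient designs are refused with the
offending columns named; a small configurable ridge can be supplied for
separated data and its use is recorded. `nnet::multinom` serves as an
independent cross-check in the tests (agreement to 1e−6 on twenty panels),
never as the estimator.

Reported fit quantities are Wald odds-ratio intervals `exp(b ± z·se)`
(matching the symmetric printed intervals of the reference table), −2LL,
likelihood-ratio tests between nested models, and McFadden's pseudo-R²
`1 − LL/LL₀` with the closed-form intercept-only LL₀. The published analysis
says only "R²"; McFadden is the standard choice for multinomial logit and is
the one implemented.

## Prediction and the reference odds ratios

`softmax_probabilities()` maps the three linear predictors to the four-way
probability vector with max-subtraction for numerical stability, so a
predictor of +1000 saturates without overflow. `probability_table()`
evaluates a fixed covariate profile (default: male, born in Sweden, age
26–30, high-school education) over the period × inpatient grid for each
origin state — the layout of the published stratified table.

`reference_ors()` stores the published two-decimal odds ratios for all three
models, and `coefficients_from_ors()` injects them as log-odds coefficients.
Two-decimal rounding matters: the Disabled intercept 0.02 spans 0.015–0.025,
which alone moves some Disabled cells by more than ±0.7 percentage points.
Reproduction of the published probability cells is therefore expected only
to about ±1 percentage point, and the tests assert exactly that. Output
tables are rounded half-up to one decimal, mirroring the published format.

## The synthetic register generator

`generate_cohort()` is first-class, tested code, not a fixture. It emulates
the register extract the analysis would consume:

* covariate marginals default to the published baseline description (52.6 %
  male, 24.9 % lower education, 74.7 % born in Sweden); factors are drawn
  independently because only marginals are published. Age groups are
  weighted (0.30/0.27/0.23/0.20) to match the reported mean baseline age of
  about 29.5 years.
* baseline states are drawn from the exact published position counts
  (≈ 25.4 % Jobless); the fine position within a state is sampled with
  weights proportional to the published position counts, so all nine
  classifier branches are exercised.
* transitions at the follow-up years follow the configured ground-truth
  coefficients (default: the published Model 3 odds ratios) through the same
  softmax machinery the predictor uses; states are carried forward between
  follow-up years.
* education upgrades one level with probability 0.02 per year, taking the
  Higher share from about 16 % to about 31 % over 15 years as in the
  published cohort description.
* inpatient days per person-year are zero-inflated geometric (any-care
  probability by current state, day count 1 + Geometric(0.25)); the Jobless
  any-care rate 0.0705/year makes about 86 % of two-year baseline windows
  care-free, matching the published 86.4 %. The kernel's inpatient covariate
  uses the per-period median among positive two-year windows of everyone
  still under follow-up; the panel builder later recomputes the median on
  the baseline-Jobless subset, so the two can differ marginally at small n —
  a deliberate, documented approximation that does not affect the
  parameter-recovery tests, which use `simulate_trajectories()` directly.
* censoring arises both from the kernel's Censored outcome (realised as
  death/emigration/old-age pension) and from small per-year death and
  emigration hazards; no record exists after a death or emigration year, and
  re-immigration never re-enters the cohort.
* each intended state is rendered into register variables constructed to be
  classification-consistent (e.g. intended long-term unemployed ⇒
  unemployment days ≥ the six-month cut with sub-threshold earnings), with
  moderate noise on the non-triggering fields. Configurations that cannot be
  rendered consistently (e.g. a non-positive earnings threshold) are
  rejected. The round-trip classifier test requires ≥ 99 % agreement between
  intended and classified states; in practice agreement is exact.

What the generator does **not** emulate: benefit rules in monetary detail
(replacement rates, caps), within-year spell timing, joint covariate
dependence, duration dependence beyond first order, or real macro-level
shocks. Passing tests therefore demonstrate correctness of the machinery
under the stated model, not fidelity of any particular coefficient to the
real Swedish labour market.

## Numerical and design choices

* Currency is abstract; the earnings threshold defaults to 1 and all
  monetary amounts scale relative to it (the real statistical-agency
  threshold varies by year and is not published).
* A value exactly at the period median is ≤ median, as the category
  definition states.
* `kernel_to_coefficients()` gives the closed-form saturated Model 1
  coefficients for any strictly positive homogeneous kernel; the tests use
  it both to drive simulations and to verify that fitted intercepts
  reproduce count ratios exactly (e.g. origin-Jobless counts 82/100/10/8
  force intercept odds ratios 0.82/0.10/0.08).
* Simulation sizes in the test suite — 50,000 persons × 5 periods for
  Model 3 parameter recovery, 200 replicates of 600 persons for interval
  coverage, 150 null replicates for the likelihood-ratio χ²(3) check —
  were chosen so that Monte-Carlo error is comfortably below the assertion
  margins while a full run stays in the tens of seconds.
* All randomness flows through explicit seeds; identical configuration and
  seed give byte-identical pipeline output.

## Limitations

Printed-OR mode inherits the two-decimal rounding of its source and cannot
recover the unrounded coefficients; which published probability cells were
computed from unrounded values explains residual discrepancies of up to
about one percentage point. The estimator covariance is the inverse observed
information; with repeated person-periods and model misspecification a
sandwich or cluster correction would differ, but is out of scope by design.
Empirical transition tables for origins with no observations report zero
columns rather than failing.
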