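---
title: "A decision-tree/Markov model for procalcitonin-guided antibiotic prescribing in hospitalized COVID-19 patients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-tree/Markov model for procalcitonin-guided antibiotic prescribing in hospitalized COVID-19 patients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the model

During the first wave of the COVID-19 pandemic many UK hospitals introduced
baseline procalcitonin (PCT) testing — a blood biomarker of bacterial
infection — to guide antibiotic decisions in people hospitalized with
COVID-19. `pctcea` implements a patient-level economic evaluation of that
policy: given a propensity-weighted two-arm cohort (PCT tested at baseline
versus not), it estimates the incremental quality-adjusted life years
(QALYs) and costs of baseline testing and the probability that testing is
cost-effective at a given willingness-to-pay threshold.

The model has two phases.

**Decision-tree phase (year 1).** Each patient's first year is valued
directly from their observed hospitalization. Alive time is survival capped
at 365.25 days, valued at the age/sex population-norm utility $u_0$; each
day in a general ward, in ICU, and on antibiotics subtracts a utility
decrement:

$$\mathrm{QALY}_{\mathrm{DT}} \;=\; u_0\,\frac{\min(s,\,365.25)}{365.25}
\;-\; \frac{0.36\,d_{\mathrm{ward}} + 0.58\,d_{\mathrm{ICU}} + 0.05\,d_{\mathrm{abx}}}{365.25},$$

where $s$ is survival in days and $d_\bullet$ are days in each state.
Decrements are additive and may overlap (an ICU day on antibiotics incurs
both): each component's expected QALY loss then factors as mean days ×
decrement / 365.25, which is the identity the acceptance tests verify.
Costs are per-day ward and ICU costs, a per-test PCT cost, antibiotic drug
costs from micro-costing (below), and a per-prescription antimicrobial-
resistance (AMR) surcharge. No discounting is applied inside year 1.

**Markov phase (lifetime).** Patients alive at one year enter an annual-
cycle alive/dead model. Survival follows an age/sex life table of annual
death probabilities $q(a)$; cycle $k$ contributes
$\left[\prod_{j=0}^{k-1}(1-q(a_0+j))\right] u(a_0+k)\,(1+r)^{-k}$ with
$r = 3\%$ per year, until a terminal age (110) where death is certain.
No costs accrue after year 1, so the lifetime horizon changes only the QALY
side of the comparison. A half-cycle (trapezoid) correction is available
(`half_cycle_correction = TRUE`) but off by default; the default treats
each cycle's survival as end-of-cycle occupancy, the simpler and more
conservative convention for a model whose comparisons difference out most
of the bias.

**Uncertainty.** Patients are resampled with replacement within arm
(carrying their propensity weights), weighted arm means are recomputed, and
the draws of $(\Delta E, \Delta C)$ yield percentile confidence intervals,
the cost-effectiveness plane, and acceptability curves
$\mathrm{CEAC}(\lambda) = \Pr(\lambda\,\Delta E - \Delta C > 0)$ over
$\lambda \in [0, 50\,000]$ £/QALY. Ties count as not cost-effective; they
have measure zero for continuous outcomes. Resampling individuals within
arm is the default because the weights arrive per patient; a pooled
resampling switch exists for sensitivity. The ratio $\Delta C/\Delta E$ has
a percentile interval too, reported with the usual caveat that ratio
intervals spanning quadrants are descriptive only.

## Key parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| Ward utility decrement | 0.36 | /day | subtracted from $u_0$ |
| ICU utility decrement | 0.58 | /day | |
| Antibiotic utility decrement | 0.05 | /day | days on ≥1 antibiotic |
| Ward cost | £487.50 × 1.025 | /day | national reference value plus a 2.5% inflation uplift |
| ICU cost | £2386 | /day | |
| PCT test cost | £15.20 | /test | |
| AMR surcharge | £2.12 | /prescription | switchable to per-dose |
| Discount rate | 3% | /year | Markov-phase utilities only |
| Willingness to pay | £20 000 | /QALY | headline threshold |

All are overridable through `econ_params()`. One known tension is worth
recording: group-level tables published for this policy question imply a
ward day nearer £400 once divided through by mean ward days, while the
national reference value with its uplift is close to £500/day. The package
defaults to the reference value, and no acceptance check depends on
ward-cost reproduction.

## Antibiotic micro-costing

Free-text drug names are normalized by an ordered rule table (regular
expressions for shorthands and misspellings, a blocklist of common
non-antibiotics), then a unique-prefix match (≥5 characters) and a
single-edit fuzzy match against the canonical lexicon; the first matching
step wins, so adding a rule never changes the result for inputs an earlier
rule already matched. Doses parse as value + unit with synonyms
("500 millilitres" → 500 mL, grams → mg). Prices come from a two-tier
table: the primary tier (modelled on actual-purchase-price extracts) is
preferred over the indicative tier (list prices); within a tier an exact
dose match wins, otherwise the prescribed dose may be assembled as the
smallest integer multiple $k \ge 2$ of a listed dose at $k$ × unit price,
ties broken by lowest cost. Unmatched records are flagged, never silently
zero-priced; the per-patient "coverage fraction" reports the share of
antibiotic records successfully costed (conventionally 1 when a patient has
none). The bundled price table and rule file are editable synthetic
fixtures with the documented structure, not extracts of the versioned
national sources.

## What the synthetic cohort emulates

`simulate_cohort()` generates the kind of data the analysis consumes, with
defaults calibrated so expected weighted arm summaries match the published
group tables: 26% baseline-PCT; mean ward days 9.28/10.7
(PCT / no-PCT), ICU days 2.55/2.68, antibiotic days 5.94/6.78, PCT tests
2.24/0.694; in-hospital death 0.309/0.301; one-year post-discharge death
0.385/0.395; age ≈ 70, 56% male.

Choices made where only means are published:

* **Ward days** are negative binomial (dispersion `size_ward = 1.5`,
  chosen so the implied standard deviation ≈ 8–9 days is consistent with
  the published confidence-interval widths), giving the long right tail
  seen in real stay distributions.
* **ICU days** are zero-inflated (20% of patients have any ICU episode, a
  judgement call exposed in `p_any_icu`) with a *shifted negative binomial*
  (1 + NB) for positive stays. A rounded gamma was considered and rejected:
  rounding biases the mean, and the generator's contract is that configured
  means are exact in expectation so calibration checks can use plain
  Monte-Carlo error bounds.
* **Weights** stand in for propensity-score-matching weights: Gamma with
  mean 1 (`weight_shape = 4`, CV = 0.5), positive and right-skewed.
* **Mortality timing.** In-hospital deaths end survival at the end of stay.
  Post-discharge deaths are uniform between discharge and day 365 — only
  the one-year probability is published, and a uniform density adds no
  structure we cannot defend. Survivors are censored at day 366, just past
  the one-year horizon; only the indicator "alive at one year" enters the
  model, so the placeholder value is inert.
* **Antibiotic records** split each patient's antibiotic days into 1–3
  sequential courses of lexicon drugs with realistic dose strings. Names
  are corrupted at rate 0.3 (case changes, truncations, single-character
  typos, clinical shorthands). Every corruption is verified to normalize
  back to its source — a typo that would collide with a similarly spelled
  drug (cefuroxime/cefotaxime) falls back to a case variant — so
  normalization coverage in the synthetic data reflects the dose-matching
  path, not irrecoverable names. Small rates of unparseable ("one tablet")
  and off-list doses leave a few percent of records uncosted, comparable to
  the high-but-imperfect coverage seen in practice.
* **What it does not emulate.** Cosmetic covariates (comorbidities, IMD
  decile) do not drive outcomes; there is no residual confounding, no
  within-patient correlation between stay length and mortality beyond the
  structural links above, and no contaminating subpopulation of full-year
  ward stays (robustness tests plant those explicitly). Passing calibration
  tests therefore demonstrates correct estimation under the assumed data
  model, not robustness to real-data pathologies.

One structural point: the in-hospital death probability is applied
unconditionally among the hospitalized, while the one-year death
probability is conditional on discharge. The published transition and
survival tables can be read two ways on this point (their unconditional
one-year survival equals the discharged-branch probability, which the
branch product contradicts); the package adopts the conditional reading
consistently, and its transition-probability estimator measures exactly
what the generator encodes.

## Data cleaning

Lengths of stay derive from day offsets: total = discharge − max(test
date, admission); ICU = ICU discharge − max(test date, ICU admission), 0
with no episode; ward = total − ICU. Day differences are exclusive of the
start day, so same-day admission and discharge is 0 days. Negative derived
stays are treated as missing. Exclusion rules run in a fixed order
(missing ICU stay, missing total stay, missing survival, ICU > total,
total > survival); each removed patient is attributed to the *first*
matching rule, and an any-match tally is reported alongside because
violations can overlap. Exclusion is idempotent, and every surviving record
satisfies `icu ≤ total ≤ survival` exactly. Nothing is imputed.

## Numerical choices and degenerate inputs

* Utility-norm lookup falls back to the nearest band at extreme ages; ages
  below 16 are a validation error (adult cohort).
* A missing life-table age inside the needed range is a validation error,
  not an interpolation.
* `icer()` returns an explicit undefined flag at $\Delta E = 0$ rather than
  an infinity.
* Empty arms error; an all-excluded cohort warns and returns an empty
  result rather than failing.
* Bootstrap draws with B = 1 and degenerate one-patient arms are rejected
  (two patients per arm minimum).
* QALYs in year 1 may be negative when daily decrements exceed baseline
  utility; this is permitted by construction.

## Problem sizes

The test-suite and acceptance runs use cohorts of n = 5000 for stochastic
calibration checks (three Monte-Carlo standard errors of the weighted
estimator), n = 150–2000 elsewhere, and B = 2000 bootstrap iterations with
a documented 3σ Monte-Carlo tolerance; the headline-analysis convention of
B = 100 000 is available by argument. These sizes make each check's
sampling error explicit rather than relying on large-sample coincidence.

## Limitations

* The lifetime phase models mortality and population-norm utility only: no
  readmission, long-COVID morbidity, or AMR health effects (AMR enters as a
  cost), and no costs after year 1.
* Bundled life table, utility norms and price table are synthetic
  stand-ins; analyses of real data should supply the current national
  resources via the loader paths.
* The propensity weights are taken as given (or synthesized); the package
  neither estimates nor diagnoses them.
* Frequency of dosing must arrive as an integer doses-per-day field;
  free-text frequency parsing is out of scope.
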