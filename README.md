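# pctcea

Cost-effectiveness analysis of baseline procalcitonin (PCT) testing to
guide antibiotic prescribing in people hospitalized with COVID-19.

PCT is a blood biomarker of bacterial infection. Hospitals that tested it
at baseline hoped to withhold antibiotics safely from COVID-19 patients
without bacterial co-infection. Whether that policy is *cost-effective*
turns on small between-arm differences in ward and ICU days, antibiotic
exposure and survival, each carrying a utility decrement and a unit cost.
`pctcea` is for health economists and methodologists who want that
evaluation as a tested, reusable patient-level pipeline rather than a
one-off script: a seeded synthetic-cohort generator, the cleaning and
exclusion rules, antibiotic micro-costing from free-text prescriptions, a
two-phase economic model, and weight-carrying bootstrap uncertainty.

## The model

Year 1 is a decision tree valued directly from each patient's observed
course: with survival $s$, baseline population-norm utility $u_0$ and days
$d_{\text{ward}}, d_{\text{ICU}}, d_{\text{abx}}$ in each state,

$$\mathrm{QALY}_{\mathrm{DT}} = u_0\,\frac{\min(s, 365.25)}{365.25}
 - \frac{0.36\,d_{\text{ward}} + 0.58\,d_{\text{ICU}} + 0.05\,d_{\text{abx}}}{365.25},$$

with costs of £499.69/ward day, £2386/ICU day, £15.20/PCT test, matched
drug prices per dose, and £2.12 AMR surcharge per prescription. Patients
alive at one year enter an annual-cycle alive/dead Markov phase driven by
an age/sex life table, accruing norm utilities discounted at 3%/year (no
costs after year 1). Incremental QALYs and costs of baseline testing are
bootstrapped within arm (patients carry their propensity weights), giving
the ICER $\Delta C/\Delta E$, the cost-effectiveness plane, and
acceptability curves $\Pr(\lambda \Delta E - \Delta C > 0)$ for
$\lambda \in [0, 50\,000]$ £/QALY.

## Worked example

```r
library(pctcea)

coh <- simulate_cohort(cohort_gen_params(n_patients = 2000, seed = 42))
fit <- pct_cea(coh, B = 1000, seed = 42)
fit
#> Cost-effectiveness of baseline procalcitonin testing
#>   2000 patients after exclusions (0 removed); antibiotic costing coverage 97.0%
#>   Decision-tree horizon:  dQALY +0.0401, dCost GBP -1348, ICER GBP -33589/QALY (dominant)
#>   Lifetime horizon:       dQALY +0.6206, dCost GBP -1348, ICER GBP -2173/QALY (dominant)
#>   P(cost-effective at GBP 20 000/QALY): 0.975 (1-year), 0.977 (lifetime); B = 1000
```

The baseline-PCT arm gains QALYs (shorter ward/ICU stays, fewer antibiotic
days) *and* costs less, so the point estimate is dominant — a negative ICER
quadrant where the ratio itself is not informative; the acceptability
probabilities carry the uncertainty statement. The fitted object exposes
the per-arm weighted summary table with bootstrap CIs (`summary(fit)`),
decision-tree transition probabilities (`fit$transitions`):

```r
subset(fit$transitions, arm == "baseline_pct")
#>           arm         from           to probability
#>  baseline_pct hospitalized         dead   0.2752793
#>  baseline_pct hospitalized   discharged   0.7247207
#>  baseline_pct   discharged         dead   0.3548965
#>  baseline_pct   discharged markov_phase   0.6451035
```

plus `coef(fit)`, `plot(fit)` (CE plane and CEACs), and the raw draws.
`run_pipeline()` drives the same fit from a YAML config and writes the
transition/summary/CE-plane/CEAC tables, an exclusion log and a run
manifest as CSVs/JSON, with optional `*_robust.csv` outputs after removing
full-year general-ward outliers.

Real cohorts enter through `read_cohort()` (a patients CSV plus a
long-format antibiotic CSV); the bundled price table, life table and
utility norms are synthetic stand-ins that can be replaced by file path.

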