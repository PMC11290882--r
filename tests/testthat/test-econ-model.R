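params <- econ_params()

test_that("baseline utility looks up bands with extreme-age fallback", {
  expect_equal(baseline_utility(c(40, 90), c("male", "male"), toy_norms(0.8)),
               c(0.8, 0.8))
  norms <- load_utility_norms()
  top <- norms$utility[norms$sex == "female" &
                         norms$age_high == max(norms$age_high)]
  expect_equal(baseline_utility(200, "female", norms), top)
  expect_error(baseline_utility(12, "male", norms), ">= 16")
})

test_that("decision-tree closed form equals a day-by-day accumulation oracle", {
  norms <- toy_norms(0.8)
  cases <- expand.grid(ward = c(0, 7, 40), icu = c(0, 3), abx = c(0, 5),
                       survival = c(10.5, 200, 366, 400))
  cases <- cases[cases$ward + cases$icu <= cases$survival, ]
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    pat <- toy_patient(ward = cs$ward, icu = cs$icu, survival = cs$survival,
                       pct = 3)
    costed <- data.frame(total_drug_cost = 1.5, amr_cost = 2.12,
                         abx_days = cs$abx)
    out <- decision_tree_outcomes(pat, costed, params, norms)
    oracle <- dt_oracle(0.8, cs$ward, cs$icu, cs$abx, cs$survival, 3, params)
    expect_equal(out$qalys_dt, oracle$qalys, tolerance = 1e-9)
    expect_equal(out$cost_ward + out$cost_icu + out$cost_pct,
                 oracle$cost, tolerance = 1e-9)
    expect_equal(out$cost_total,
                 out$cost_ward + out$cost_icu + out$cost_pct +
                   out$cost_drugs + out$cost_amr)  # additivity is exact
    expect_lte(out$qalys_dt, 0.8)
  }
})

test_that("a patient with no stays, tests or antibiotics accrues baseline utility and no cost", {
  out <- decision_tree_outcomes(toy_patient(survival = 400), NULL, params,
                                toy_norms(0.73))
  expect_equal(out$qalys_dt, 0.73)
  expect_equal(out$cost_total, 0)
  expect_true(out$alive_at_1y)
})

test_that("decrements can push year-1 QALYs below zero when they exceed baseline utility", {
  # daily ICU decrement (0.58) above a low baseline utility
  out <- decision_tree_outcomes(toy_patient(icu = 300, survival = 300), NULL,
                                params, toy_norms(0.55))
  expect_lt(out$qalys_dt, 0)
})

test_that("Markov engine matches the discounted annuity under deterministic survival", {
  # alive exactly N years: q = 0 until the horizon, then certain death
  N <- 10
  a0 <- 70
  lt <- toy_life_table(function(a) if (a < a0 + N) 0 else 1)
  u <- 0.8
  r <- 0.03
  got <- markov_lifetime_qalys(a0, "male", lt, toy_norms(u),
                               econ_params(discount_rate = r))
  annuity <- u * sum((1 + r)^-(1:N))
  expect_equal(got, annuity, tolerance = 1e-12)
  # immediate certain death gives zero QALYs
  lt1 <- toy_life_table(function(a) 1)
  expect_equal(markov_lifetime_qalys(a0, "male", lt1, toy_norms(u), params), 0)
})

test_that("Markov engine matches the geometric-series oracle under constant hazard", {
  q <- 0.2
  u <- 0.75
  a0 <- 60
  lt <- toy_life_table(function(a) q)
  got <- markov_lifetime_qalys(a0, "female", lt, toy_norms(u),
                               econ_params(discount_rate = 0))
  K <- 110 - a0 + 1  # cycles until the table's terminal age
  oracle <- u * (1 - q) / q * (1 - (1 - q)^K)
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("discounting only lowers Markov QALYs, monotonically in the rate", {
  lt <- load_life_table()
  norms <- load_utility_norms()
  rates <- c(0, 0.015, 0.03, 0.06)
  for (sex in c("male", "female")) {
    q <- vapply(rates, function(r)
      markov_lifetime_qalys(71, sex, lt, norms, econ_params(discount_rate = r)),
      numeric(1))
    expect_true(all(diff(q) < 0))
    expect_true(all(q >= 0))
  }
  expect_error(
    markov_lifetime_qalys(70, "male",
                          toy_life_table(function(a) 0.1,
                                         ages = c(0:75, 80:110)),
                          toy_norms(), econ_params()),
    "life table")
})

test_that("transition probabilities are weighted, complementary and weighting-consistent", {
  p <- rbind(
    toy_patient(id = 1L, died_in_hospital = TRUE, survival = 10, ward = 10,
                weight = 2),
    toy_patient(id = 2L, survival = 100, ward = 5, weight = 1),
    toy_patient(id = 3L, survival = 400, ward = 5, weight = 1),
    toy_patient(id = 4L, arm = "no_baseline_pct", died_in_hospital = TRUE,
                survival = 3, ward = 3),
    toy_patient(id = 5L, arm = "no_baseline_pct", survival = 400, ward = 2))
  tr <- estimate_transition_probabilities(p)
  get <- function(a, from, to)
    tr$probability[tr$arm == a & tr$from == from & tr$to == to]
  expect_equal(get("baseline_pct", "hospitalized", "dead"), 0.5)  # w 2 of 4
  expect_equal(get("baseline_pct", "discharged", "markov_phase"), 0.5)
  for (a in unique(tr$arm)) {
    expect_equal(get(a, "hospitalized", "dead") + get(a, "hospitalized", "discharged"), 1)
    expect_equal(get(a, "discharged", "dead") + get(a, "discharged", "markov_phase"), 1)
  }
  # equal weights match duplicated records
  dup <- rbind(p, p)
  dup$patient_id <- seq_len(nrow(dup))
  tr2 <- estimate_transition_probabilities(dup)
  expect_equal(tr$probability, tr2$probability)
  expect_error(estimate_transition_probabilities(p[p$arm == "baseline_pct", ]),
               "empty")
})
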