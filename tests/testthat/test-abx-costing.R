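rules <- load_abx_rules()
prices <- load_price_table()

test_that("free-text names normalize case-, whitespace- and shorthand-insensitively", {
  expect_equal(normalize_abx_name("AMOXICILLIN ", rules), "amoxicillin")
  expect_equal(normalize_abx_name("  Co-Amox", rules), "co-amoxiclav")
  expect_equal(normalize_abx_name("tazocin", rules), "piperacillin-tazobactam")
  expect_equal(normalize_abx_name("pip-taz", rules), "piperacillin-tazobactam")
  expect_equal(normalize_abx_name("paracetamol", rules), "non_antibiotic")
  expect_equal(normalize_abx_name("levothyroxine", rules), "unrecognized")
  # single-character typos resolve by fuzzy match when unambiguous
  expect_equal(normalize_abx_name("amoxicilin", rules), "amoxicillin")
  expect_equal(normalize_abx_name("vancomycinn", rules), "vancomycin")
})

test_that("normalization is order-stable: earlier-matching inputs are unaffected by added rules", {
  inputs <- c("amox", "tazocin", "gent", "CIPROFLOXACIN", "flagyl")
  before <- normalize_abx_name(inputs, rules)
  extended <- rbind(rules,
                    data.frame(pattern = "^amoxi?foo$", canonical = "amoxicillin",
                               action = "map"))
  class(extended) <- class(rules)
  after <- normalize_abx_name(inputs, extended)
  expect_identical(before, after)
})

test_that("dose strings parse with unit synonyms and grams convert to milligrams", {
  d <- parse_dose(c("500 millilitres", "1 g", "250mg", "1.2 g", "one tablet",
                    "4000 units"))
  expect_equal(d$value[1:4], c(500, 1000, 250, 1200))
  expect_equal(d$unit[1:4], c("mL", "mg", "mg", "mg"))
  expect_false(d$parsed[5])
  expect_equal(d$unit[6], "units")
})

test_that("price matching prefers the primary tier and exact doses", {
  tab <- toy_price_table(data.frame(
    canonical_name = rep("drugx", 3),
    dose_value = c(500, 500, 250), dose_unit = "mg",
    unit_price = c(0.10, 0.90, 0.04),
    tier = c("primary", "indicative", "primary"), stringsAsFactors = FALSE))
  m <- match_price("drugx", 500, "mg", tab)
  expect_true(m$matched)
  expect_equal(m$per_dose_cost, 0.10)
  expect_equal(m$tier, "primary")
  expect_false(match_price("drugx", 300, "mg", tab)$matched)
  expect_false(match_price("drugx", 500, "mL", tab)$matched)
})

test_that("unavailable doses assemble as the smallest integer multiple, ties by cost", {
  tab <- toy_price_table(data.frame(
    canonical_name = "drugx", dose_value = c(250, 500), dose_unit = "mg",
    unit_price = c(0.04, 0.10), tier = "primary", stringsAsFactors = FALSE))
  m <- match_price("drugx", 1000, "mg", tab)
  expect_equal(m$multiple, 2L)          # 2 x 500, not 4 x 250
  expect_equal(m$per_dose_cost, 0.20)
  # brute-force oracle over all (entry, k) combinations
  brute <- function(dose) {
    cand <- expand.grid(i = 1:2, k = 2:40)
    cand$dose <- tab$dose_value[cand$i] * cand$k
    cand$cost <- tab$unit_price[cand$i] * cand$k
    hit <- cand[cand$dose == dose, ]
    hit[order(hit$k, hit$cost), ][1, c("k", "cost")]
  }
  for (dose in c(750, 1000, 1500, 2000, 3000)) {
    m <- match_price("drugx", dose, "mg", tab)
    b <- brute(dose)
    expect_equal(m$multiple, b$k, label = paste("k for dose", dose))
    expect_equal(m$per_dose_cost, b$cost, label = paste("cost for dose", dose))
  }
})

test_that("matched cost is never below the cheapest single listed dose", {
  set.seed(31)
  for (r in 1:200) {
    nm <- sample(abx_lexicon(), 1)
    entries <- prices[prices$canonical_name == nm, ]
    dose <- sample(c(entries$dose_value, entries$dose_value * sample(2:4, 1),
                     sample(50:5000, 1)), 1)
    m <- match_price(nm, dose, "mg", prices)
    if (m$matched) expect_gte(m$per_dose_cost, min(entries$unit_price))
  }
})

test_that("per-patient antibiotic costing totals drug, AMR and day counts", {
  expect_equal(cost_antibiotics(NULL), cost_antibiotics(data.frame()[0, ]))
  empty <- cost_antibiotics(NULL)
  expect_equal(empty$total_drug_cost, 0)
  expect_equal(empty$coverage_fraction, 1)

  tab <- toy_price_table(data.frame(
    canonical_name = "amoxicillin", dose_value = 500, dose_unit = "mg",
    unit_price = 0.10, tier = "primary", stringsAsFactors = FALSE))
  recs <- data.frame(
    name_text = c("amoxicillin", "mystery-drug", "paracetamol"),
    dose_text = c("500 mg", "10 mg", "1 g"),
    frequency_per_day = c(2L, 1L, 4L),
    days = c(5L, 3L, 2L), stringsAsFactors = FALSE)
  out <- cost_antibiotics(recs, rules, tab, econ_params())
  expect_equal(out$total_drug_cost, 0.10 * 2 * 5)       # only the matched record
  expect_equal(out$coverage_fraction, 0.5)              # 1 of 2 antibiotic records
  expect_equal(out$n_prescriptions, 2L)                 # paracetamol excluded
  expect_equal(out$amr_cost, 2.12 * 2)
  expect_equal(out$abx_days, 8)                         # sequential convention

  # three prescriptions cost 3 x 2.12 in AMR surcharge
  recs3 <- data.frame(name_text = rep("amoxicillin", 3), dose_text = "500 mg",
                      frequency_per_day = 1L, days = 2L, stringsAsFactors = FALSE)
  expect_equal(cost_antibiotics(recs3, rules, tab)$amr_cost, 6.36)
  # per-dose switch: 3 records x 1/day x 2 days = 6 doses
  pd <- econ_params(amr_unit = "per_dose")
  expect_equal(cost_antibiotics(recs3, rules, tab, pd)$amr_cost, 2.12 * 6)

  # overlapping courses: antibiotic days are the union of calendar days
  recs_ov <- data.frame(name_text = rep("amoxicillin", 2), dose_text = "500 mg",
                        frequency_per_day = 1L, days = c(5L, 4L),
                        start_day = c(0L, 3L), stringsAsFactors = FALSE)
  expect_equal(cost_antibiotics(recs_ov, rules, tab)$abx_days, 7)
})

test_that("bulk cohort costing agrees with the per-patient operation", {
  coh <- simulate_cohort(cohort_gen_params(n_patients = 150, seed = 13))
  params <- econ_params()
  bulk <- pctcea:::cost_cohort_antibiotics(coh$patients, coh$abx, rules,
                                           prices, params)
  for (i in sample(nrow(coh$patients), 40)) {
    id <- coh$patients$patient_id[i]
    one <- cost_antibiotics(coh$abx[coh$abx$patient_id == id, ], rules,
                            prices, params)
    expect_equal(bulk$total_drug_cost[i], one$total_drug_cost)
    expect_equal(bulk$amr_cost[i], one$amr_cost)
    expect_equal(bulk$abx_days[i], one$abx_days)
  }
})
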