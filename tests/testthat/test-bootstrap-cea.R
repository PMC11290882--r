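make_outcomes <- function(n_per_arm = 60, seed = 8) {
  set.seed(seed)
  p <- rbind(
    do.call(rbind, lapply(seq_len(n_per_arm), function(i)
      toy_patient(id = i, ward = rpois(1, 8), survival = sample(c(50, 400), 1),
                  pct = rpois(1, 2), weight = rgamma(1, 4, 4)))),
    do.call(rbind, lapply(seq_len(n_per_arm), function(i)
      toy_patient(id = n_per_arm + i, arm = "no_baseline_pct",
                  ward = rpois(1, 10), survival = sample(c(50, 400), 1),
                  pct = rpois(1, 1), weight = rgamma(1, 4, 4)))))
  decision_tree_outcomes(p, NULL, econ_params(), toy_norms(0.8))
}

test_that("weighted summary reduces to hand arithmetic", {
  p <- rbind(toy_patient(id = 1L, ward = 0, weight = 1, survival = 400),
             toy_patient(id = 2L, ward = 4, weight = 3, survival = 400))
  out <- decision_tree_outcomes(p, NULL, econ_params(), toy_norms(0.8))
  s <- weighted_summary(out, econ_params())
  expect_equal(s$mean[s$stat == "ward_days"], 3)  # weights (1,3) on (0,4)
  # survival is capped at the horizon before averaging
  expect_equal(s$mean[s$stat == "survival_capped"], 365.25)
  out$psm_weight <- c(1, 1)
  s2 <- weighted_summary(out, econ_params())
  expect_equal(s2$mean[s2$stat == "ward_days"], 2)
  out$psm_weight <- c(0, 0)
  expect_error(weighted_summary(out, econ_params()), "weights")
})

test_that("bootstrap is seeded, preserves arm sizes and weight positivity", {
  out <- make_outcomes()
  d1 <- bootstrap_cea(out, B = 50, seed = 4)
  d2 <- bootstrap_cea(out, B = 50, seed = 4)
  expect_identical(d1$arm_means, d2$arm_means)
  d3 <- bootstrap_cea(out, B = 50, seed = 5)
  expect_false(identical(d1$dC, d3$dC))
  expect_equal(dim(d1$arm_means$baseline_pct)[1], 50)
  expect_true(all(is.finite(d1$dC)))
  expect_error(bootstrap_cea(out[out$arm == "baseline_pct", ][1, ], B = 10),
               "at least 2")
  expect_error(bootstrap_cea(out, B = 0), "B must be")
})

test_that("bootstrap means converge to the point estimate (3 sigma at B = 2000)", {
  out <- make_outcomes(n_per_arm = 80)
  pt <- weighted_summary(out, econ_params())
  d <- bootstrap_cea(out, B = 2000, seed = 12)
  for (a in c("baseline_pct", "no_baseline_pct")) {
    for (st in c("qalys_dt", "cost_total", "ward_days")) {
      draws <- d$arm_means[[a]][, st]
      mc_se <- stats::sd(draws) / sqrt(length(draws))
      target <- pt$mean[pt$arm == a & pt$stat == st]
      expect_lt(abs(mean(draws) - target), 3 * mc_se + 1e-12,
                label = sprintf("bootstrap mean of %s in %s", st, a))
    }
  }
  # percentile CI contains the point estimate on well-behaved data
  ci <- stats::quantile(d$dC, c(0.025, 0.975))
  pt_dC <- pt$mean[pt$arm == "baseline_pct" & pt$stat == "cost_total"] -
    pt$mean[pt$arm == "no_baseline_pct" & pt$stat == "cost_total"]
  expect_gte(pt_dC, ci[[1]])
  expect_lte(pt_dC, ci[[2]])
})

test_that("single-patient-per-arm bootstrap degenerates to the point estimate", {
  p <- rbind(toy_patient(id = 1L, ward = 5, survival = 400, weight = 2),
             toy_patient(id = 2L, arm = "no_baseline_pct", ward = 9,
                         survival = 400, weight = 1),
             toy_patient(id = 3L, ward = 5, survival = 400, weight = 2),
             toy_patient(id = 4L, arm = "no_baseline_pct", ward = 9,
                         survival = 400, weight = 1))
  out <- decision_tree_outcomes(p, NULL, econ_params(), toy_norms(0.8))
  d <- bootstrap_cea(out, B = 1, seed = 1)
  pt <- weighted_summary(out, econ_params())
  expect_equal(unname(d$arm_means$baseline_pct[1, "ward_days"]),
               pt$mean[pt$arm == "baseline_pct" & pt$stat == "ward_days"])
})

test_that("ICER reports ratio, dominance quadrant and the undefined flag", {
  r <- icer(dE = 1, dC = 100)
  expect_equal(r$icer, 100)
  expect_equal(r$quadrant, "trade-off")
  r <- icer(dE = 0.14, dC = -870)
  expect_lt(r$icer, 0)
  expect_equal(r$quadrant, "dominant")
  expect_equal(icer(dE = -0.1, dC = 50)$quadrant, "dominated")
  r0 <- icer(dE = 0, dC = 5)
  expect_true(r0$undefined)
  expect_true(is.na(r0$icer))
})

test_that("CEAC follows its definition, endpoints and limits", {
  # enumerable two-draw case
  expect_equal(ceac(dE = c(1, 1), dC = c(10, 30), 20)$p_cost_effective, 0.5)
  set.seed(99)
  dE <- rnorm(400, 0.05, 0.1)
  dC <- rnorm(400, -100, 400)
  cv <- ceac(dE, dC, thresholds = c(0, 1000, 20000, 1e9))
  expect_equal(cv$p_cost_effective[1], mean(dC < 0))
  expect_equal(cv$p_cost_effective[4], mean(dE > 0))
  expect_true(all(cv$p_cost_effective >= 0 & cv$p_cost_effective <= 1))
  expect_equal(ceac(dE = abs(dE), dC = -abs(dC), 500)$p_cost_effective, 1)
  expect_error(ceac(dE, dC, c(5, 1)), "ascending")
})

test_that("full-year ward outliers are removed and counted per arm", {
  coh <- simulate_cohort(cohort_gen_params(n_patients = 2000, seed = 17))
  qc <- apply_exclusions(coh)
  clean <- qc$cohort
  expect_identical(remove_ward_outliers(clean)$patients, clean$patients)

  # plant exactly 13 full-year general-ward stays in the no-PCT arm
  idx <- which(clean$patients$arm == "no_baseline_pct")[1:13]
  p <- clean$patients
  start <- pmax(p$admission_day[idx], p$covid_test_day[idx])
  p$discharge_day[idx] <- start + 366 +
    ifelse(is.na(p$icu_out_day[idx]), 0, p$icu_out_day[idx] - start)
  p$survival_days[idx] <- 800
  p$died_in_hospital[idx] <- FALSE
  clean$patients <- derive_lengths_of_stay(p)
  clean$patients$ward_days <- clean$patients$total_days - clean$patients$icu_days
  trimmed <- remove_ward_outliers(clean)
  removed <- attr(trimmed, "removed_by_arm")
  expect_equal(unname(removed["no_baseline_pct"]), 13L)
  expect_equal(unname(removed["baseline_pct"]), 0L)
  expect_equal(nrow(trimmed$patients), nrow(clean$patients) - 13L)
  expect_true(all(trimmed$patients$ward_days < 365.25))
  # the boundary case is removed
  one <- toy_patient(ward = 365.25, survival = 400)
  expect_equal(nrow(remove_ward_outliers(one)), 0L)
})
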