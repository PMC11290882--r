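#' Economic model parameters
#'
#' Bundles every unit cost, utility decrement and modelling constant used by
#' the decision-tree and Markov phases in one validated container. Defaults
#' are the NHS reference values used in the published COVID-19 evaluation:
#' per-day utility decrements of 0.36 (general ward), 0.58 (ICU) and 0.05
#' (antibiotic treatment); a general-ward day of GBP 487.50 uplifted 2.5% for
#' inflation; an ICU day of GBP 2386; GBP 15.20 per procalcitonin test; and an
#' antimicrobial-resistance surcharge of GBP 2.12 per prescription. Utilities
#' in the Markov phase are discounted at 3% per year.
#'
#' @param u_ward_decrement Daily utility decrement for a general-ward day.
#' @param u_icu_decrement Daily utility decrement for an ICU day.
#' @param u_abx_decrement Daily utility decrement for a day on antibiotics.
#' @param c_ward_base Daily general-ward cost before inflation uplift (GBP).
#' @param ward_uplift Multiplicative inflation uplift applied to `c_ward_base`.
#' @param c_icu_per_day Daily ICU cost (GBP).
#' @param c_pct_per_test Cost per procalcitonin test (GBP).
#' @param c_amr_per_prescription Antimicrobial-resistance surcharge (GBP),
#'   applied per unit given by `amr_unit`.
#' @param amr_unit Either `"per_record"` (one antibiotic course = one
#'   prescription, the default) or `"per_dose"` (every administered dose).
#' @param discount_rate Annual discount rate applied to Markov-phase utilities.
#' @param days_per_year Days in a model year (365.25).
#' @param dt_horizon_days Decision-tree horizon in days (one year).
#' @param wtp_threshold Willingness-to-pay threshold (GBP per QALY) used when
#'   reporting a headline probability of cost-effectiveness.
#' @param threshold_grid Willingness-to-pay grid for the acceptability curve.
#' @param markov_max_age Age at which the life table forces death.
#' @param half_cycle_correction Apply a half-cycle correction in the Markov
#'   phase? Off by default.
#'
#' @return An object of class `econ_params` (a validated list).
#' @examples
#' p <- econ_params()
#' p$c_ward_per_day  # 487.50 * 1.025
#' @export
econ_params <- function(u_ward_decrement = 0.36,
                        u_icu_decrement = 0.58,
                        u_abx_decrement = 0.05,
                        c_ward_base = 487.50,
                        ward_uplift = 0.025,
                        c_icu_per_day = 2386,
                        c_pct_per_test = 15.20,
                        c_amr_per_prescription = 2.12,
                        amr_unit = c("per_record", "per_dose"),
                        discount_rate = 0.03,
                        days_per_year = 365.25,
                        dt_horizon_days = 365.25,
                        wtp_threshold = 20000,
                        threshold_grid = seq(0, 50000, by = 500),
                        markov_max_age = 110L,
                        half_cycle_correction = FALSE) {
  amr_unit <- match.arg(amr_unit)
  p <- list(
    u_ward_decrement = u_ward_decrement,
    u_icu_decrement = u_icu_decrement,
    u_abx_decrement = u_abx_decrement,
    c_ward_base = c_ward_base,
    ward_uplift = ward_uplift,
    c_ward_per_day = c_ward_base * (1 + ward_uplift),
    c_icu_per_day = c_icu_per_day,
    c_pct_per_test = c_pct_per_test,
    c_amr_per_prescription = c_amr_per_prescription,
    amr_unit = amr_unit,
    discount_rate = discount_rate,
    days_per_year = days_per_year,
    dt_horizon_days = dt_horizon_days,
    wtp_threshold = wtp_threshold,
    threshold_grid = threshold_grid,
    markov_max_age = as.integer(markov_max_age),
    half_cycle_correction = isTRUE(half_cycle_correction)
  )
  for (f in c("u_ward_decrement", "u_icu_decrement", "u_abx_decrement")) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || p[[f]] < 0 || p[[f]] > 1)
      stop("econ_params: '", f, "' must be a single value in [0, 1]", call. = FALSE)
  }
  for (f in c("c_ward_base", "c_icu_per_day", "c_pct_per_test",
              "c_amr_per_prescription", "dt_horizon_days", "days_per_year")) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || p[[f]] < 0)
      stop("econ_params: '", f, "' must be a single non-negative value", call. = FALSE)
  }
  if (p$discount_rate < 0 || p$discount_rate >= 1)
    stop("econ_params: 'discount_rate' must be in [0, 1)", call. = FALSE)
  if (any(diff(p$threshold_grid) <= 0) || any(p$threshold_grid < 0))
    stop("econ_params: 'threshold_grid' must be non-negative and ascending", call. = FALSE)
  structure(p, class = "econ_params")
}

#' @export
print.econ_params <- function(x, ...) {
  cat("Economic model parameters\n")
  cat(sprintf("  Utility decrements (per day): ward %.2f, ICU %.2f, antibiotics %.2f\n",
              x$u_ward_decrement, x$u_icu_decrement, x$u_abx_decrement))
  cat(sprintf("  Unit costs: ward GBP %.2f/day (incl. %.1f%% uplift), ICU GBP %.0f/day\n",
              x$c_ward_per_day, 100 * x$ward_uplift, x$c_icu_per_day))
  cat(sprintf("  PCT GBP %.2f/test; AMR GBP %.2f %s\n",
              x$c_pct_per_test, x$c_amr_per_prescription,
              ifelse(x$amr_unit == "per_record", "per prescription", "per dose")))
  cat(sprintf("  Discount rate %.1f%%/year; decision-tree horizon %.2f days; max age %d\n",
              100 * x$discount_rate, x$dt_horizon_days, x$markov_max_age))
  invisible(x)
}

#' Synthetic cohort generator parameters
#'
#' Settings for [simulate_cohort()]. Defaults are calibrated so that, in
#' expectation, per-arm weighted summaries match the published group tables:
#' 26% of patients tested at baseline; mean general-ward stays of 9.28 / 10.7
#' days (baseline-PCT / no-baseline-PCT), ICU stays of 2.55 / 2.68 days,
#' antibiotic days of 5.94 / 6.78, PCT test counts of 2.24 / 0.694;
#' in-hospital death probabilities 0.309 / 0.301 and 1-year post-discharge
#' death probabilities 0.385 / 0.395; mean age about 70 and 56% male.
#'
#' Arm-indexed arguments are length-2 vectors ordered
#' `c(baseline_pct, no_baseline_pct)`.
#'
#' @param n_patients Number of patients (at least 2).
#' @param p_baseline_pct Probability of being in the baseline-PCT arm.
#' @param mean_ward_days,mean_icu_days,mean_abx_days,mean_pct_tests Per-arm
#'   target means.
#' @param p_any_icu Per-arm probability of any ICU episode.
#' @param p_hospital_death Per-arm probability of dying in hospital.
#' @param p_postdischarge_death_1y Per-arm probability, conditional on
#'   discharge, of dying before one year.
#' @param age_mean,age_sd,male_fraction Demographics.
#' @param size_ward,size_icu,size_abx Negative-binomial dispersion (`size`)
#'   parameters of the stay/antibiotic-day distributions; smaller is
#'   longer-tailed.
#' @param weight_shape Shape of the Gamma distribution (scaled to mean 1)
#'   standing in for propensity-score-matching weights.
#' @param text_corruption_rate Probability an antibiotic name is emitted as a
#'   misspelling, shorthand or case variant rather than its canonical form.
#' @param p_unparseable_dose Probability a dose string is free text that the
#'   dose parser cannot read (e.g. "one tablet").
#' @param p_off_table_dose Probability a dose is drawn off the price list (not
#'   an exact entry nor an integer multiple), leaving the record uncosted.
#' @param seed Integer seed; every draw in [simulate_cohort()] flows from it.
#'
#' @return An object of class `cohort_gen_params`.
#' @export
cohort_gen_params <- function(n_patients = 5000L,
                              p_baseline_pct = 0.26,
                              mean_ward_days = c(9.28, 10.7),
                              mean_icu_days = c(2.55, 2.68),
                              mean_abx_days = c(5.94, 6.78),
                              mean_pct_tests = c(2.24, 0.694),
                              p_any_icu = c(0.20, 0.20),
                              p_hospital_death = c(0.309, 0.301),
                              p_postdischarge_death_1y = c(0.385, 0.395),
                              age_mean = 70,
                              age_sd = 15,
                              male_fraction = 0.56,
                              size_ward = 1.5,
                              size_icu = 1.2,
                              size_abx = 2.0,
                              weight_shape = 4,
                              text_corruption_rate = 0.30,
                              p_unparseable_dose = 0.02,
                              p_off_table_dose = 0.01,
                              seed = 1L) {
  p <- list(
    n_patients = as.integer(n_patients),
    p_baseline_pct = p_baseline_pct,
    mean_ward_days = mean_ward_days,
    mean_icu_days = mean_icu_days,
    mean_abx_days = mean_abx_days,
    mean_pct_tests = mean_pct_tests,
    p_any_icu = p_any_icu,
    p_hospital_death = p_hospital_death,
    p_postdischarge_death_1y = p_postdischarge_death_1y,
    age_mean = age_mean,
    age_sd = age_sd,
    male_fraction = male_fraction,
    size_ward = size_ward,
    size_icu = size_icu,
    size_abx = size_abx,
    weight_shape = weight_shape,
    text_corruption_rate = text_corruption_rate,
    p_unparseable_dose = p_unparseable_dose,
    p_off_table_dose = p_off_table_dose,
    seed = as.integer(seed)
  )
  if (is.na(p$n_patients) || p$n_patients < 2L)
    stop("cohort_gen_params: 'n_patients' must be an integer >= 2", call. = FALSE)
  probs <- c("p_baseline_pct", "p_any_icu", "p_hospital_death",
             "p_postdischarge_death_1y", "male_fraction",
             "text_corruption_rate", "p_unparseable_dose", "p_off_table_dose")
  for (f in probs) {
    if (!is.numeric(p[[f]]) || anyNA(p[[f]]) || any(p[[f]] < 0) || any(p[[f]] > 1))
      stop("cohort_gen_params: '", f, "' must lie in [0, 1]", call. = FALSE)
  }
  arm2 <- c("mean_ward_days", "mean_icu_days", "mean_abx_days", "mean_pct_tests",
            "p_any_icu", "p_hospital_death", "p_postdischarge_death_1y")
  for (f in arm2) {
    if (length(p[[f]]) != 2L)
      stop("cohort_gen_params: '", f, "' must have length 2 (baseline_pct, no_baseline_pct)",
           call. = FALSE)
  }
  nonneg <- c("mean_ward_days", "mean_icu_days", "mean_abx_days", "mean_pct_tests",
              "age_mean", "age_sd")
  for (f in nonneg) {
    if (!is.numeric(p[[f]]) || anyNA(p[[f]]) || any(p[[f]] < 0))
      stop("cohort_gen_params: '", f, "' must be non-negative", call. = FALSE)
  }
  for (f in c("size_ward", "size_icu", "size_abx", "weight_shape")) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || p[[f]] <= 0)
      stop("cohort_gen_params: '", f, "' must be a single positive value", call. = FALSE)
  }
  # baseline-PCT patients have at least one test by definition
  if (p$mean_pct_tests[1] < 1)
    stop("cohort_gen_params: 'mean_pct_tests' in the baseline-PCT arm must be >= 1",
         call. = FALSE)
  if (is.na(p$seed)) stop("cohort_gen_params: 'seed' must be an integer", call. = FALSE)
  structure(p, class = "cohort_gen_params")
}

#' @export
print.cohort_gen_params <- function(x, ...) {
  cat("Synthetic cohort generator parameters\n")
  cat(sprintf("  n = %d patients, P(baseline PCT) = %.3f, seed = %d\n",
              x$n_patients, x$p_baseline_pct, x$seed))
  cat(sprintf("  Target means (PCT / no PCT): ward %.2f/%.2f d, ICU %.2f/%.2f d, abx %.2f/%.2f d, tests %.2f/%.3f\n",
              x$mean_ward_days[1], x$mean_ward_days[2],
              x$mean_icu_days[1], x$mean_icu_days[2],
              x$mean_abx_days[1], x$mean_abx_days[2],
              x$mean_pct_tests[1], x$mean_pct_tests[2]))
  cat(sprintf("  Mortality: in-hospital %.3f/%.3f, post-discharge (1 y) %.3f/%.3f\n",
              x$p_hospital_death[1], x$p_hospital_death[2],
              x$p_postdischarge_death_1y[1], x$p_postdischarge_death_1y[2]))
  invisible(x)
}
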