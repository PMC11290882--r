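# shared fixtures, all built in code

# flat utility norms: one band, both sexes, constant utility
toy_norms <- function(u = 0.8) {
  structure(data.frame(age_low = c(16, 16), age_high = c(110, 110),
                       sex = c("male", "female"), utility = c(u, u),
                       stringsAsFactors = FALSE),
            class = c("utility_norms", "data.frame"))
}

# life table with a caller-supplied annual death probability per age
toy_life_table <- function(qfun, ages = 0:110) {
  q <- vapply(ages, qfun, numeric(1))
  structure(data.frame(age = rep(ages, 2),
                       sex = rep(c("male", "female"), each = length(ages)),
                       qx = rep(q, 2), stringsAsFactors = FALSE),
            class = c("life_table", "data.frame"))
}

toy_price_table <- function(df) {
  structure(df, class = c("price_table", "data.frame"))
}

# one-row cleaned patient with derived stays
toy_patient <- function(ward = 0, icu = 0, survival = 400, pct = 0,
                        age = 70, sex = "male", weight = 1,
                        arm = "baseline_pct", id = 1L,
                        died_in_hospital = FALSE) {
  data.frame(patient_id = id, arm = arm, age = age, sex = sex,
             psm_weight = weight, ward_days = ward, icu_days = icu,
             total_days = ward + icu, survival_days = survival,
             died_in_hospital = died_in_hospital, pct_test_count = pct,
             stringsAsFactors = FALSE)
}

# raw-offset patient row for the QC derivations
toy_raw <- function(admission = 0, test = 0, discharge = 10,
                    icu_in = NA, icu_out = NA, survival = 400, id = 1L,
                    arm = "baseline_pct", weight = 1) {
  data.frame(patient_id = id, arm = arm, age = 70, sex = "male",
             psm_weight = weight,
             admission_day = admission, covid_test_day = test,
             discharge_day = discharge,
             icu_in_day = as.integer(icu_in), icu_out_day = as.integer(icu_out),
             survival_days = survival, died_in_hospital = FALSE,
             pct_test_count = 0L, stringsAsFactors = FALSE)
}

# independent day-by-day accumulation of year-1 QALYs and costs
dt_oracle <- function(u0, ward, icu, abx, survival, pct, params) {
  dpy <- params$days_per_year
  t_alive <- min(survival, params$dt_horizon_days)
  qal <- 0
  d <- 0
  while (d + 1 <= t_alive) {  # whole days alive
    qal <- qal + u0 / dpy
    d <- d + 1
  }
  qal <- qal + u0 * (t_alive - d) / dpy  # fractional remainder
  for (k in seq_len(round(ward))) qal <- qal - params$u_ward_decrement / dpy
  for (k in seq_len(round(icu))) qal <- qal - params$u_icu_decrement / dpy
  for (k in seq_len(round(abx))) qal <- qal - params$u_abx_decrement / dpy
  cost <- 0
  for (k in seq_len(round(ward))) cost <- cost + params$c_ward_per_day
  for (k in seq_len(round(icu))) cost <- cost + params$c_icu_per_day
  for (k in seq_len(round(pct))) cost <- cost + params$c_pct_per_test
  list(qalys = qal, cost = cost)
}
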