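#' Bundled life table and utility norms
#'
#' Loaders for the two demographic resources the lifetime model needs: an
#' age/sex life table of annual death probabilities in the national-life-table
#' column convention (`age`, `sex`, `qx`), and age-band/sex population utility
#' norms (`age_low`, `age_high`, `sex`, `utility`). The bundled files are
#' synthetic stand-ins with the same structure and realistic magnitudes
#' (Gompertz-Makeham mortality; EQ-5D-like norms); the national resources
#' they emulate are versioned external publications and are not shipped.
#'
#' @param path Path to a CSV in the documented dialect; defaults to the
#'   bundled synthetic file.
#' @return A validated data frame of class `life_table` or `utility_norms`.
#' @name demographic_resources
NULL

#' @rdname demographic_resources
#' @export
load_life_table <- function(path = system.file("extdata",
                                               "life_table_synthetic.csv",
                                               package = "pctcea")) {
  if (!nzchar(path) || !file.exists(path))
    stop("life table file not found: '", path, "'", call. = FALSE)
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age", "sex", "qx") %in% names(lt)))
    stop("life table must have columns age, sex, qx", call. = FALSE)
  if (any(lt$qx < 0 | lt$qx > 1))
    stop("life table: qx must lie in [0, 1]", call. = FALSE)
  structure(lt, class = c("life_table", "data.frame"))
}

#' @rdname demographic_resources
#' @export
load_utility_norms <- function(path = system.file("extdata",
                                                  "utility_norms_synthetic.csv",
                                                  package = "pctcea")) {
  if (!nzchar(path) || !file.exists(path))
    stop("utility norms file not found: '", path, "'", call. = FALSE)
  un <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age_low", "age_high", "sex", "utility") %in% names(un)))
    stop("utility norms must have columns age_low, age_high, sex, utility", call. = FALSE)
  if (any(un$utility < -0.594 | un$utility > 1))
    stop("utility norms must lie within EQ-5D bounds [-0.594, 1]", call. = FALSE)
  structure(un, class = c("utility_norms", "data.frame"))
}

#' Baseline utility from population norms
#'
#' Looks up the age/sex population-norm utility for each patient. Ages above
#' the top band take the top band's value (and symmetrically at the bottom),
#' provided the patient is an adult.
#'
#' @param age Numeric vector of ages in years (all at least 16).
#' @param sex Character vector, `"male"` or `"female"`.
#' @param norms A `utility_norms` table.
#' @return Numeric vector of baseline utilities.
#' @examples
#' baseline_utility(70, "male", load_utility_norms())
#' @export
baseline_utility <- function(age, sex, norms = load_utility_norms()) {
  if (any(is.na(age)) || any(age < 16))
    stop("baseline_utility: ages must be >= 16 (adult cohort)", call. = FALSE)
  if (!all(sex %in% c("male", "female")))
    stop("baseline_utility: sex must be 'male' or 'female'", call. = FALSE)
  vapply(seq_along(age), function(i) {
    b <- norms[norms$sex == sex[i], , drop = FALSE]
    b <- b[order(b$age_low), , drop = FALSE]
    hit <- which(age[i] >= b$age_low & age[i] <= b$age_high)
    if (length(hit) > 0L) return(b$utility[hit[1L]])
    if (age[i] > max(b$age_high)) return(b$utility[nrow(b)])
    b$utility[1L]
  }, numeric(1))
}

#' Per-patient decision-tree (year 1) outcomes
#'
#' Accrues QALYs and costs over the one-year decision-tree phase for cleaned
#' patient records. Alive time is survival capped at the one-year horizon,
#' valued at the baseline population-norm utility; each general-ward, ICU and
#' antibiotic day then subtracts its per-day utility decrement (decrements
#' are additive and may overlap). Costs are per-day ward and ICU costs,
#' per-test PCT costs, and the drug plus antimicrobial-resistance costs
#' computed by [cost_antibiotics()]. The Markov component of the returned
#' outcomes is zero; see [markov_lifetime_qalys()].
#'
#' @param patients Cleaned patients data frame (post [apply_exclusions()])
#'   with `ward_days`, `icu_days`, `survival_days`, `pct_test_count`, `age`,
#'   `sex`.
#' @param costed Data frame with one row per patient (aligned) and columns
#'   `total_drug_cost`, `amr_cost`, `abx_days`; e.g. from aggregating
#'   [cost_antibiotics()] over the cohort. `NULL` means no antibiotics.
#' @param params An [econ_params()] object.
#' @param norms A `utility_norms` table.
#' @return Data frame of class `patient_outcomes`: QALY components
#'   (`qalys_dt`, `qalys_markov` = 0, `qalys_total`), itemized costs
#'   (`cost_ward`, `cost_icu`, `cost_pct`, `cost_drugs`, `cost_amr`,
#'   `cost_total`), `baseline_utility`, `alive_at_1y`, and carried-through
#'   identifiers, arm, weight, age and sex.
#' @export
decision_tree_outcomes <- function(patients, costed = NULL,
                                   params = econ_params(),
                                   norms = load_utility_norms()) {
  n <- nrow(patients)
  if (is.null(costed)) {
    costed <- data.frame(total_drug_cost = numeric(n), amr_cost = numeric(n),
                         abx_days = numeric(n))
  }
  stopifnot(nrow(costed) == n)
  u0 <- baseline_utility(patients$age, patients$sex, norms)
  dpy <- params$days_per_year
  t_alive <- pmin(patients$survival_days, params$dt_horizon_days)
  qalys_dt <- u0 * t_alive / dpy -
    (patients$ward_days * params$u_ward_decrement +
       patients$icu_days * params$u_icu_decrement +
       costed$abx_days * params$u_abx_decrement) / dpy
  cost_ward <- patients$ward_days * params$c_ward_per_day
  cost_icu <- patients$icu_days * params$c_icu_per_day
  cost_pct <- patients$pct_test_count * params$c_pct_per_test
  cost_drugs <- costed$total_drug_cost
  cost_amr <- costed$amr_cost
  out <- data.frame(
    patient_id = patients$patient_id,
    arm = patients$arm,
    psm_weight = patients$psm_weight,
    age = patients$age,
    sex = patients$sex,
    baseline_utility = u0,
    ward_days = patients$ward_days,
    icu_days = patients$icu_days,
    abx_days = costed$abx_days,
    pct_tests = patients$pct_test_count,
    survival_capped = t_alive,
    alive_at_1y = patients$survival_days > params$dt_horizon_days,
    qalys_dt = qalys_dt,
    qalys_markov = 0,
    qalys_total = qalys_dt,
    cost_ward = cost_ward,
    cost_icu = cost_icu,
    cost_pct = cost_pct,
    cost_drugs = cost_drugs,
    cost_amr = cost_amr,
    cost_total = cost_ward + cost_icu + cost_pct + cost_drugs + cost_amr,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("patient_outcomes", "data.frame"))
}

#' Discounted lifetime QALYs in the Markov phase
#'
#' For a patient alive at one year, runs the annual-cycle two-state
#' (alive/dead) Markov model: in cycle k the probability of still being
#' alive is the product of one-year survival probabilities from the life
#' table at the attained ages, the cycle's QALY is that survival probability
#' times the population-norm utility at the attained age, discounted at the
#' annual rate. Cycles run until the life table's terminal age, where the
#' death probability is one. No costs accrue in the Markov phase. With
#' `half_cycle_correction` the cycle QALY is averaged with the previous
#' cycle's survival (trapezoid rule).
#'
#' @param age Age in years at entry to the Markov phase (i.e. at one year).
#' @param sex `"male"` or `"female"`.
#' @param life_table A `life_table` of annual death probabilities.
#' @param norms A `utility_norms` table.
#' @param params An [econ_params()] object (`discount_rate`,
#'   `markov_max_age`, `half_cycle_correction`).
#' @return Discounted QALYs (a single number).
#' @examples
#' markov_lifetime_qalys(71, "female")
#' @export
markov_lifetime_qalys <- function(age, sex, life_table = load_life_table(),
                                  norms = load_utility_norms(),
                                  params = econ_params()) {
  lt <- life_table[life_table$sex == sex, , drop = FALSE]
  qx <- stats::setNames(lt$qx, lt$age)
  max_age <- min(params$markov_max_age, max(lt$age))
  a0 <- floor(age)
  if (a0 > max_age) return(0)
  ages <- a0:max_age
  if (!all(as.character(ages) %in% names(qx)))
    stop("life table has no entry for ages ",
         paste(setdiff(ages, as.numeric(names(qx))), collapse = ", "),
         " (", sex, ")", call. = FALSE)
  q <- unname(qx[as.character(ages)])
  surv <- cumprod(1 - q)          # P(alive at end of cycle k), k = 1..K
  k <- seq_along(ages)
  u <- baseline_utility(pmin(a0 + k, max_age), rep(sex, length(k)), norms)
  disc <- (1 + params$discount_rate)^(-k)
  occupancy <- if (params$half_cycle_correction) {
    (c(1, surv[-length(surv)]) + surv) / 2
  } else {
    surv
  }
  sum(occupancy * u * disc)
}

#' Decision-tree transition probabilities from a cohort
#'
#' Estimates, per arm, the weighted transition probabilities of the
#' decision-tree phase: hospitalized to dead (in-hospital death) versus
#' discharged, and — conditional on discharge — dead before one year versus
#' entry into the Markov phase. Complementary pairs sum to one within each
#' branch.
#'
#' @param outcomes A `patient_outcomes` data frame joined with the cleaned
#'   cohort's `died_in_hospital` flag, or a cleaned patients data frame with
#'   `died_in_hospital`, `survival_days`, `psm_weight`, `arm`; weights are
#'   `psm_weight`.
#' @param dt_horizon_days One-year horizon used to define Markov entry.
#' @return Data frame with one row per (arm, from, to) transition and a
#'   `probability` column, of class `transition_probs`.
#' @export
estimate_transition_probabilities <- function(outcomes,
                                              dt_horizon_days = 365.25) {
  p <- outcomes
  need <- c("arm", "psm_weight", "died_in_hospital", "survival_days")
  if (!all(need %in% names(p)))
    stop("estimate_transition_probabilities needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  arms <- c("baseline_pct", "no_baseline_pct")
  rows <- list()
  for (a in arms) {
    d <- p[p$arm == a, , drop = FALSE]
    if (nrow(d) == 0L) stop("arm '", a, "' is empty", call. = FALSE)
    w <- d$psm_weight
    p_hd <- sum(w * d$died_in_hospital) / sum(w)
    disc <- !d$died_in_hospital
    if (!any(disc)) {
      p_markov <- NA_real_
    } else {
      wd <- w[disc]
      p_markov <- sum(wd * (d$survival_days[disc] > dt_horizon_days)) / sum(wd)
    }
    rows[[a]] <- data.frame(
      arm = a,
      from = c("hospitalized", "hospitalized", "discharged", "discharged"),
      to = c("dead", "discharged", "dead", "markov_phase"),
      probability = c(p_hd, 1 - p_hd, 1 - p_markov, p_markov),
      stringsAsFactors = FALSE
    )
  }
  structure(do.call(rbind, c(rows, list(make.row.names = FALSE))),
            class = c("transition_probs", "data.frame"))
}
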