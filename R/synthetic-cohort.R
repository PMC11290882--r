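#' Simulate a synthetic hospitalized-COVID-19 cohort
#'
#' Generates a seeded patient-level cohort with the statistical structure the
#' cost-effectiveness analysis assumes: two arms (baseline procalcitonin
#' testing vs none), long-tailed ward and ICU stay distributions, in-hospital
#' and one-year post-discharge mortality, per-patient positive
#' propensity-score-matching weights, PCT test counts, and messy free-text
#' antibiotic records. Defaults (see [cohort_gen_params()]) are calibrated so
#' expected per-arm weighted summaries match the published group tables.
#'
#' Ward days are drawn from a negative binomial (integer days, long tail);
#' ICU days from a zero-inflated shifted negative binomial (a Bernoulli ICU
#' admission, then `1 + NB` days), which keeps the configured arm mean exact
#' after integer rounding. In-hospital deaths receive a survival time equal
#' to the end of stay; post-discharge deaths occur uniformly between
#' discharge and day 365; survivors are censored at day 366, just beyond the
#' one-year decision-tree horizon. Antibiotic courses are emitted
#' sequentially, so a patient's calendar days on antibiotics equal the summed
#' course lengths.
#'
#' @param params A [cohort_gen_params()] object.
#' @return An object of class `pct_cohort`: a list with `patients` (one row
#'   per patient, raw day offsets and demographics) and `abx` (long-format
#'   antibiotic records keyed by `patient_id`), plus the generating
#'   parameters.
#' @examples
#' coh <- simulate_cohort(cohort_gen_params(n_patients = 50, seed = 42))
#' table(coh$patients$arm)
#' @export
simulate_cohort <- function(params = cohort_gen_params()) {
  if (!inherits(params, "cohort_gen_params"))
    params <- do.call(cohort_gen_params, as.list(params))
  set.seed(params$seed)
  n <- params$n_patients
  lex <- abx_lexicon()
  prices <- load_price_table()
  rules <- load_abx_rules()

  arm_idx <- ifelse(stats::runif(n) < params$p_baseline_pct, 1L, 2L)
  arm <- c("baseline_pct", "no_baseline_pct")[arm_idx]

  age <- round(stats::rnorm(n, params$age_mean, params$age_sd))
  age <- pmin(pmax(age, 16), 105)
  sex <- ifelse(stats::runif(n) < params$male_fraction, "male", "female")
  # cosmetic covariates; they do not drive outcomes
  n_comorbid <- stats::rpois(n, 2)
  imd_decile <- sample.int(10, n, replace = TRUE)

  psm_weight <- stats::rgamma(n, shape = params$weight_shape,
                              rate = params$weight_shape)
  psm_weight <- pmax(psm_weight, 1e-6)

  ward <- stats::rnbinom(n, size = params$size_ward,
                         mu = params$mean_ward_days[arm_idx])
  any_icu <- stats::runif(n) < params$p_any_icu[arm_idx]
  mu_icu_pos <- params$mean_icu_days / params$p_any_icu  # mean given an ICU stay
  icu <- integer(n)
  icu[any_icu] <- 1L + stats::rnbinom(sum(any_icu), size = params$size_icu,
                                      mu = pmax(mu_icu_pos[arm_idx[any_icu]] - 1, 1e-9))
  total <- ward + icu

  died_hosp <- stats::runif(n) < params$p_hospital_death[arm_idx]
  died_post <- !died_hosp &
    stats::runif(n) < params$p_postdischarge_death_1y[arm_idx]
  # a discharge on/after day 365 cannot be followed by a death within year 1
  died_post[died_post & total >= 365] <- FALSE
  survival <- numeric(n)
  survival[died_hosp] <- total[died_hosp]
  survival[died_post] <- total[died_post] +
    stats::runif(sum(died_post)) * (365 - total[died_post])
  alive <- !died_hosp & !died_post
  survival[alive] <- pmax(366, total[alive] + 1)

  pct_tests <- integer(n)
  b <- arm_idx == 1L
  pct_tests[b] <- 1L + stats::rpois(sum(b), params$mean_pct_tests[1] - 1)
  pct_tests[!b] <- stats::rpois(sum(!b), params$mean_pct_tests[2])

  # day offsets; stays derive back to the drawn values because the episode
  # start is max(test, admission) and the ICU episode starts there too
  admission_day <- sample(0:2, n, replace = TRUE)
  covid_test_day <- admission_day + sample(c(-1L, 0L, 1L), n, replace = TRUE,
                                           prob = c(0.15, 0.7, 0.15))
  covid_test_day <- pmax(covid_test_day, 0L)
  start <- pmax(admission_day, covid_test_day)
  discharge_day <- start + total
  icu_in_day <- ifelse(any_icu, start, NA_integer_)
  icu_out_day <- ifelse(any_icu, start + icu, NA_integer_)

  patients <- data.frame(
    patient_id = seq_len(n),
    arm = arm,
    age = as.numeric(age),
    sex = sex,
    psm_weight = psm_weight,
    n_comorbid = n_comorbid,
    imd_decile = imd_decile,
    admission_day = admission_day,
    covid_test_day = covid_test_day,
    discharge_day = discharge_day,
    icu_in_day = as.integer(icu_in_day),
    icu_out_day = as.integer(icu_out_day),
    survival_days = survival,
    died_in_hospital = died_hosp,
    pct_test_count = pct_tests,
    stringsAsFactors = FALSE
  )

  abx_days <- stats::rnbinom(n, size = params$size_abx,
                             mu = params$mean_abx_days[arm_idx])
  abx <- generate_abx_records(abx_days, lex, prices, rules,
                              corruption_rate = params$text_corruption_rate,
                              p_unparseable = params$p_unparseable_dose,
                              p_off_table = params$p_off_table_dose)

  structure(list(patients = patients, abx = abx, params = params),
            class = "pct_cohort")
}

# split each patient's antibiotic days into 1-3 sequential courses and emit
# free-text name/dose records with the configured corruption rates
generate_abx_records <- function(abx_days, lex, prices, rules,
                                 corruption_rate, p_unparseable, p_off_table) {
  out <- vector("list", length(abx_days))
  primary <- prices[prices$tier == "primary", , drop = FALSE]
  for (i in seq_along(abx_days)) {
    d <- abx_days[i]
    if (d <= 0) next
    n_courses <- min(d, sample.int(3L, 1L, prob = c(0.5, 0.35, 0.15)))
    cuts <- sort(sample.int(d - 1L, n_courses - 1L))
    lens <- diff(c(0L, cuts, d))
    drugs <- sample(lex, n_courses, replace = TRUE)
    rec <- data.frame(
      patient_id = i,
      name_text = character(n_courses),
      dose_text = character(n_courses),
      frequency_per_day = sample(c(1L, 2L, 3L, 4L), n_courses, replace = TRUE,
                                 prob = c(0.2, 0.35, 0.3, 0.15)),
      days = as.integer(lens),
      start_day = as.integer(cumsum(c(0L, lens[-n_courses]))),
      stringsAsFactors = FALSE
    )
    for (j in seq_len(n_courses)) {
      rec$name_text[j] <- corrupt_abx_name(drugs[j], corruption_rate,
                                           seed = NULL, rules = rules)
      u <- stats::runif(1)
      doses <- primary$dose_value[primary$canonical_name == drugs[j]]
      if (length(doses) == 0L)
        doses <- prices$dose_value[prices$canonical_name == drugs[j]]
      if (u < p_unparseable) {
        rec$dose_text[j] <- sample(c("one tablet", "as directed", "stat dose"), 1L)
      } else if (u < p_unparseable + p_off_table) {
        rec$dose_text[j] <- paste(max(doses) + 7, "mg")
      } else {
        dv <- doses[sample.int(length(doses), 1L)]
        if (stats::runif(1) < 0.15) dv <- dv * sample(2:3, 1L)  # multiple of a listed dose
        rec$dose_text[j] <- if (dv >= 1000 && dv %% 1000 == 0 && stats::runif(1) < 0.5) {
          paste(dv / 1000, sample(c("g", "grams"), 1L))
        } else {
          paste(dv, sample(c("mg", "mg", "milligrams"), 1L))
        }
      }
    }
    out[[i]] <- rec
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(patient_id = integer(0), name_text = character(0),
                      dose_text = character(0), frequency_per_day = integer(0),
                      days = integer(0), start_day = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Corrupt a canonical antibiotic name
#'
#' Emits a realistic free-text variant of a canonical antibiotic name: with
#' probability `rate` one of a case change, whitespace padding, truncation,
#' a single-character typo, or a known clinical shorthand (e.g. "tazocin");
#' otherwise the input is returned unchanged. Every corruption is guaranteed
#' to normalize back to its source: a candidate that
#' [normalize_abx_name()] cannot round-trip (possible for typos of
#' similarly-spelled drugs) is replaced by a case/whitespace variant.
#'
#' @param canonical_name A name from [abx_lexicon()].
#' @param rate Corruption probability in \[0, 1\].
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param rules Normalization rules used for the round-trip guarantee.
#' @return A single free-text string.
#' @examples
#' corrupt_abx_name("amoxicillin", rate = 1, seed = 7)
#' @export
corrupt_abx_name <- function(canonical_name, rate, seed = NULL,
                             rules = load_abx_rules()) {
  lex <- unique(rules$canonical[rules$action == "map"])
  if (!canonical_name %in% lex)
    stop("'", canonical_name, "' is not in the antibiotic lexicon", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (stats::runif(1) >= rate) return(canonical_name)
  kind <- sample(c("case", "pad", "truncate", "typo", "shorthand"), 1L)
  cand <- switch(kind,
    case = sample(c(toupper(canonical_name),
                    paste0(toupper(substr(canonical_name, 1, 1)),
                           substr(canonical_name, 2, nchar(canonical_name)))), 1L),
    pad = paste0("  ", canonical_name, "  "),
    truncate = substr(canonical_name, 1,
                      max(6L, nchar(canonical_name) - sample.int(3L, 1L))),
    typo = one_char_typo(canonical_name),
    shorthand = {
      sh <- shorthand_variants(canonical_name, rules)
      if (length(sh) > 0L) sample(sh, 1L) else toupper(canonical_name)
    }
  )
  back <- normalize_abx_name(cand, rules)
  if (identical(back, canonical_name)) cand else toupper(canonical_name)
}

one_char_typo <- function(x) {
  n <- nchar(x)
  pos <- sample(2:n, 1L)
  op <- sample(c("dup", "drop", "swap"), 1L)
  ch <- substr(x, pos, pos)
  switch(op,
    dup = paste0(substr(x, 1, pos), ch, substr(x, pos + 1L, n)),
    drop = paste0(substr(x, 1, pos - 1L), substr(x, pos + 1L, n)),
    swap = if (pos < n) {
      paste0(substr(x, 1, pos - 1L), substr(x, pos + 1L, pos + 1L),
             ch, substr(x, pos + 2L, n))
    } else {
      paste0(substr(x, 1, pos), ch)
    }
  )
}

# literal shorthands recoverable from the rule table (alternation-free,
# anchored alternatives whose branches are plain words)
shorthand_variants <- function(canonical_name, rules) {
  pats <- rules$pattern[rules$action == "map" & rules$canonical == canonical_name]
  out <- character(0)
  for (p in pats) {
    p2 <- gsub("^\\^|\\$$", "", p)
    for (alt in strsplit(p2, "|", fixed = TRUE)[[1]]) {
      if (grepl("^[a-z -]+$", alt)) out <- c(out, alt)
    }
  }
  setdiff(unique(out), canonical_name)
}

#' Inject quality-control violations into a cohort
#'
#' Marks a seeded random subset of patients with each class of data problem
#' the cleaning step screens for: missing ICU length of stay, missing total
#' length of stay, missing survival time, ICU stay longer than total stay,
#' and total stay longer than survival. Violations are injected into
#' disjoint patients so the exclusion log can attribute each removal to
#' exactly one class.
#'
#' @param cohort A `pct_cohort` from [simulate_cohort()].
#' @param rates Named numeric vector of per-class rates in \[0, 1\]; names
#'   among `missing_icu_los`, `missing_total_los`, `missing_survival`,
#'   `icu_gt_total`, `total_gt_survival`. Missing names get rate 0.
#' @param seed Integer seed.
#' @return The cohort with violations applied; attribute `injected` carries
#'   the per-class tally.
#' @export
inject_qc_violations <- function(cohort, rates = c(), seed = 1L) {
  classes <- c("missing_icu_los", "missing_total_los", "missing_survival",
               "icu_gt_total", "total_gt_survival")
  r <- stats::setNames(rep(0, length(classes)), classes)
  if (length(rates) > 0) {
    bad <- setdiff(names(rates), classes)
    if (length(bad) > 0)
      stop("unknown violation class: ", paste(bad, collapse = ", "), call. = FALSE)
    if (any(rates < 0 | rates > 1))
      stop("violation rates must lie in [0, 1]", call. = FALSE)
    r[names(rates)] <- rates
  }
  set.seed(seed)
  p <- cohort$patients
  n <- nrow(p)
  pool <- sample.int(n)  # draw disjoint patients for each class
  tally <- stats::setNames(integer(length(classes)), classes)
  taken <- 0L
  for (cl in classes) {
    k <- stats::rbinom(1L, n, r[[cl]])
    k <- min(k, n - taken)
    if (k == 0L) next
    idx <- pool[(taken + 1L):(taken + k)]
    taken <- taken + k
    tally[[cl]] <- k
    if (cl == "missing_icu_los") {
      start <- pmax(p$admission_day[idx], p$covid_test_day[idx])
      p$icu_in_day[idx] <- start
      p$icu_out_day[idx] <- NA_integer_
    } else if (cl == "missing_total_los") {
      p$discharge_day[idx] <- NA_integer_
    } else if (cl == "missing_survival") {
      p$survival_days[idx] <- NA_real_
    } else if (cl == "icu_gt_total") {
      start <- pmax(p$admission_day[idx], p$covid_test_day[idx])
      p$icu_in_day[idx] <- start
      p$icu_out_day[idx] <- p$discharge_day[idx] + 3L
    } else if (cl == "total_gt_survival") {
      tot <- p$discharge_day[idx] - pmax(p$admission_day[idx], p$covid_test_day[idx])
      p$discharge_day[idx] <- p$discharge_day[idx] + 5L
      p$survival_days[idx] <- pmax(tot, 1) / 2
      p$died_in_hospital[idx] <- FALSE
    }
  }
  cohort$patients <- p
  attr(cohort, "injected") <- tally
  cohort
}

#' @export
print.pct_cohort <- function(x, ...) {
  p <- x$patients
  cat(sprintf("Synthetic COVID-19 cohort: %d patients (%d baseline PCT, %d no baseline PCT)\n",
              nrow(p), sum(p$arm == "baseline_pct"), sum(p$arm == "no_baseline_pct")))
  cat(sprintf("  %d antibiotic records; seed %d\n", nrow(x$abx), x$params$seed))
  invisible(x)
}
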