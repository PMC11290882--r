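#' Weighted per-arm summary of patient outcomes
#'
#' Propensity-weighted arm means of the quantities the analysis reports:
#' ward/ICU/antibiotic days, PCT tests, the QALY loss and cost attached to
#' each component, capped survival, probability of one-year survival,
#' baseline utility, QALYs (decision-tree only and including the Markov
#' phase) and total cost. When bootstrap draws are supplied, percentile 95%
#' confidence intervals are attached.
#'
#' @param outcomes A `patient_outcomes` data frame (see
#'   [decision_tree_outcomes()]), optionally with Markov QALYs filled in.
#' @param params An [econ_params()] object (decrements used for the QALY-loss
#'   columns).
#' @param draws Optional bootstrap draws from [bootstrap_cea()].
#' @return Data frame with columns `arm`, `stat`, `mean` and, with draws,
#'   `lo` and `hi`.
#' @export
weighted_summary <- function(outcomes, params = econ_params(), draws = NULL) {
  arms <- c("baseline_pct", "no_baseline_pct")
  rows <- list()
  for (a in arms) {
    d <- outcomes[outcomes$arm == a, , drop = FALSE]
    if (nrow(d) == 0L) next
    w <- d$psm_weight
    if (all(w == 0)) stop("weighted_summary: all weights are zero", call. = FALSE)
    X <- outcome_stat_matrix(d, params)
    m <- colSums(w * X) / sum(w)
    rows[[a]] <- data.frame(arm = a, stat = colnames(X), mean = unname(m),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(draws)) {
    out$lo <- NA_real_
    out$hi <- NA_real_
    for (a in arms) {
      D <- draws$arm_means[[a]]
      if (is.null(D)) next
      ci <- apply(D, 2L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
      i <- out$arm == a
      out$lo[i] <- ci[1L, match(out$stat[i], colnames(D))]
      out$hi[i] <- ci[2L, match(out$stat[i], colnames(D))]
    }
  }
  out
}

# per-patient statistics whose weighted means populate the report tables
outcome_stat_matrix <- function(d, params) {
  dpy <- params$days_per_year
  cbind(
    ward_days = d$ward_days,
    icu_days = d$icu_days,
    abx_days = d$abx_days,
    pct_tests = d$pct_tests,
    qloss_ward = -d$ward_days * params$u_ward_decrement / dpy,
    qloss_icu = -d$icu_days * params$u_icu_decrement / dpy,
    qloss_abx = -d$abx_days * params$u_abx_decrement / dpy,
    cost_ward = d$cost_ward,
    cost_icu = d$cost_icu,
    cost_pct = d$cost_pct,
    cost_drugs = d$cost_drugs,
    cost_amr = d$cost_amr,
    survival_capped = d$survival_capped,
    p_1y_survival = as.numeric(d$alive_at_1y),
    baseline_utility = d$baseline_utility,
    qalys_dt = d$qalys_dt,
    qalys_total = d$qalys_total,
    cost_total = d$cost_total
  )
}

#' Bootstrap the incremental cost-effectiveness quantities
#'
#' Resamples patients with replacement (within each arm by default,
#' preserving arm sizes and carrying each patient's propensity weight),
#' recomputes the weighted arm means of every reported statistic, and stores
#' the incremental QALYs and costs of baseline PCT testing versus none for
#' the decision-tree-only and decision-tree-plus-Markov horizons.
#'
#' @param outcomes A `patient_outcomes` data frame.
#' @param B Number of bootstrap iterations (at least 1; the headline analysis
#'   convention is 100 000).
#' @param seed Integer seed.
#' @param resample `"within_arm"` (default) or `"pooled"` (patients resampled
#'   from the pooled cohort, arm labels carried along).
#' @param params An [econ_params()] object.
#' @return A list of class `cea_draws`: `arm_means` (per-arm B x stat
#'   matrices), `dE_dt`, `dE_total`, `dC` (length-B vectors), `B`, `seed`.
#' @export
bootstrap_cea <- function(outcomes, B = 2000L, seed = 1L,
                          resample = c("within_arm", "pooled"),
                          params = econ_params()) {
  resample <- match.arg(resample)
  if (B < 1L) stop("bootstrap_cea: B must be >= 1", call. = FALSE)
  arms <- c("baseline_pct", "no_baseline_pct")
  idx_arm <- lapply(arms, function(a) which(outcomes$arm == a))
  names(idx_arm) <- arms
  if (any(lengths(idx_arm) < 2L))
    stop("bootstrap_cea: each arm needs at least 2 patients", call. = FALSE)
  X <- outcome_stat_matrix(outcomes, params)
  w <- outcomes$psm_weight
  set.seed(seed)
  K <- ncol(X)
  res <- lapply(arms, function(a) matrix(NA_real_, B, K,
                                         dimnames = list(NULL, colnames(X))))
  names(res) <- arms
  n_pool <- nrow(outcomes)
  for (b in seq_len(B)) {
    if (resample == "within_arm") {
      take <- lapply(idx_arm, function(ix) ix[sample.int(length(ix),
                                                         replace = TRUE)])
    } else {
      ix <- sample.int(n_pool, replace = TRUE)
      take <- lapply(arms, function(a) ix[outcomes$arm[ix] == a])
      names(take) <- arms
      if (any(lengths(take) == 0L)) {  # degenerate pooled draw: redraw
        take <- lapply(idx_arm, function(ix) ix[sample.int(length(ix),
                                                           replace = TRUE)])
      }
    }
    for (a in arms) {
      ix <- take[[a]]
      wi <- w[ix]
      res[[a]][b, ] <- colSums(wi * X[ix, , drop = FALSE]) / sum(wi)
    }
  }
  structure(list(
    arm_means = res,
    dE_dt = res$baseline_pct[, "qalys_dt"] - res$no_baseline_pct[, "qalys_dt"],
    dE_total = res$baseline_pct[, "qalys_total"] -
      res$no_baseline_pct[, "qalys_total"],
    dC = res$baseline_pct[, "cost_total"] - res$no_baseline_pct[, "cost_total"],
    B = B, seed = seed, resample = resample
  ), class = "cea_draws")
}

#' Incremental cost-effectiveness ratio and dominance quadrant
#'
#' @param dE Incremental QALYs (intervention minus comparator).
#' @param dC Incremental cost.
#' @return List with `icer` (`dC / dE`; `NA` with `undefined = TRUE` when
#'   `dE` is 0) and `quadrant`: `"dominant"` (more QALYs, lower cost),
#'   `"dominated"` (fewer QALYs, higher cost) or `"trade-off"`.
#' @examples
#' icer(dE = 0.14, dC = -870)  # dominant, negative ICER
#' @export
icer <- function(dE, dC) {
  if (dE == 0) {
    return(list(icer = NA_real_, quadrant = "trade-off", undefined = TRUE))
  }
  quadrant <- if (dE > 0 && dC < 0) "dominant"
  else if (dE < 0 && dC > 0) "dominated"
  else "trade-off"
  list(icer = dC / dE, quadrant = quadrant, undefined = FALSE)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the probability that the
#' intervention is cost-effective: the fraction of bootstrap draws with a
#' positive net monetary benefit, `lambda * dE - dC > 0` (ties count as not
#' cost-effective).
#'
#' @param dE,dC Bootstrap draws of incremental QALYs and costs.
#' @param thresholds Ascending non-negative willingness-to-pay grid
#'   (GBP/QALY).
#' @return Data frame with `threshold` and `p_cost_effective`.
#' @examples
#' ceac(dE = c(1, 1), dC = c(10, 30), thresholds = 20)$p_cost_effective  # 0.5
#' @export
ceac <- function(dE, dC, thresholds = seq(0, 50000, by = 500)) {
  if (any(thresholds < 0) || is.unsorted(thresholds, strictly = FALSE))
    stop("ceac: thresholds must be non-negative and ascending", call. = FALSE)
  p <- vapply(thresholds, function(l) mean(l * dE - dC > 0), numeric(1))
  data.frame(threshold = thresholds, p_cost_effective = p)
}

#' Remove full-year general-ward outliers
#'
#' Drops patients who spent the entire decision-tree year in a general ward
#' (`ward_days >= horizon`), the robustness analysis the long right tail of
#' ward stays motivates, and reports how many were removed from each arm.
#'
#' @param cohort A `pct_cohort`, a patients data frame, or a
#'   `patient_outcomes` data frame with `ward_days` and `arm`.
#' @param horizon Ward-day threshold (the one-year decision-tree horizon).
#' @return The input without the outliers; attribute `removed_by_arm` holds
#'   the per-arm counts.
#' @export
remove_ward_outliers <- function(cohort, horizon = 365.25) {
  p <- if (inherits(cohort, "pct_cohort")) cohort$patients else cohort
  drop <- !is.na(p$ward_days) & p$ward_days >= horizon
  removed <- table(factor(p$arm[drop], levels = c("baseline_pct",
                                                  "no_baseline_pct")))
  if (inherits(cohort, "pct_cohort")) {
    cohort$patients <- p[!drop, , drop = FALSE]
    cohort$abx <- cohort$abx[cohort$abx$patient_id %in%
                               cohort$patients$patient_id, , drop = FALSE]
    out <- cohort
  } else {
    out <- p[!drop, , drop = FALSE]
  }
  attr(out, "removed_by_arm") <- c(removed)
  out
}

# bulk antibiotic costing: one row per patient of the cleaned cohort, same
# semantics as looping cost_antibiotics() but normalizing each unique string
# and pricing each unique (name, dose) once
cost_cohort_antibiotics <- function(patients, abx, rules = load_abx_rules(),
                                    table = load_price_table(),
                                    params = econ_params()) {
  n <- nrow(patients)
  out <- data.frame(patient_id = patients$patient_id,
                    total_drug_cost = numeric(n), amr_cost = numeric(n),
                    abx_days = numeric(n), n_prescriptions = integer(n),
                    n_matched = integer(n))
  if (is.null(abx) || nrow(abx) == 0L) return(out)
  abx <- abx[abx$patient_id %in% patients$patient_id, , drop = FALSE]
  if (nrow(abx) == 0L) return(out)

  un <- unique(abx$name_text)
  canon <- normalize_abx_name(un, rules)[match(abx$name_text, un)]
  dose <- parse_dose(abx$dose_text)
  key <- paste(canon, dose$value, dose$unit)
  uk <- !duplicated(key)
  price_map <- new.env(parent = emptyenv())
  for (i in which(uk)) {
    m <- match_price(canon[i], dose$value[i], dose$unit[i], table)
    assign(key[i], m, envir = price_map)
  }
  matched <- logical(nrow(abx))
  per_dose <- numeric(nrow(abx))
  for (i in seq_len(nrow(abx))) {
    m <- get(key[i], envir = price_map)
    matched[i] <- m$matched
    per_dose[i] <- if (m$matched) m$per_dose_cost else 0
  }
  is_abx <- canon != "non_antibiotic"
  matched <- matched & is_abx
  rec_cost <- ifelse(matched, per_dose * abx$frequency_per_day * abx$days, 0)

  pid <- match(abx$patient_id, patients$patient_id)
  add_by <- function(v, subset = TRUE) {
    z <- numeric(n)
    t <- tapply(v[subset], pid[subset], sum)
    z[as.integer(names(t))] <- t
    z
  }
  out$total_drug_cost <- add_by(rec_cost)
  out$n_prescriptions <- as.integer(add_by(as.numeric(is_abx)))
  out$n_matched <- as.integer(add_by(as.numeric(matched)))
  out$amr_cost <- if (params$amr_unit == "per_dose") {
    params$c_amr_per_prescription *
      add_by(abx$frequency_per_day * abx$days * is_abx)
  } else {
    params$c_amr_per_prescription * out$n_prescriptions
  }
  # sequential-course convention: calendar antibiotic days are summed course
  # days; with start_day present, overlapping courses are unioned per patient
  if (!is.null(abx$start_day) && !anyNA(abx$start_day)) {
    for (g in split(which(is_abx), pid[is_abx])) {
      days <- unique(unlist(Map(function(s, d) if (d > 0) seq.int(s, s + d - 1L)
                                else integer(0),
                                abx$start_day[g], abx$days[g])))
      out$abx_days[pid[g[1L]]] <- length(days)
    }
  } else {
    out$abx_days <- add_by(abx$days * is_abx)
  }
  out
}

#' Fit the procalcitonin cost-effectiveness model
#'
#' The package's main entry point. Takes a patient-level cohort (typically
#' from [simulate_cohort()] or [read_cohort()]), applies the exclusion
#' rules, costs each patient's antibiotics, accrues decision-tree (year-1)
#' QALYs and costs and discounted lifetime Markov QALYs, estimates the
#' decision-tree transition probabilities, and characterizes uncertainty by
#' a propensity-weight-carrying bootstrap: incremental QALYs and costs,
#' ICERs, percentile confidence intervals and cost-effectiveness
#' acceptability curves for both the one-year and lifetime horizons.
#'
#' @param cohort A `pct_cohort`, or a patients data frame (with an `abx`
#'   data frame passed separately).
#' @param abx Long-format antibiotic records when `cohort` is a plain data
#'   frame.
#' @param params An [econ_params()] object.
#' @param rules,prices,life_table,norms Resource tables; defaults are the
#'   bundled fixtures.
#' @param B Bootstrap iterations.
#' @param seed Seed for the bootstrap.
#' @param resample Bootstrap resampling scheme, see [bootstrap_cea()].
#' @param drop_ward_outliers Remove full-year general-ward stays before
#'   fitting (the robustness analysis)?
#' @return An object of class `pct_cea`; see [summary.pct_cea()],
#'   [coef.pct_cea()], [plot.pct_cea()].
#' @examples
#' \donttest{
#' fit <- pct_cea(simulate_cohort(cohort_gen_params(n_patients = 400, seed = 2)),
#'                B = 200, seed = 2)
#' coef(fit)
#' }
#' @export
pct_cea <- function(cohort, abx = NULL, params = econ_params(),
                    rules = load_abx_rules(), prices = load_price_table(),
                    life_table = load_life_table(),
                    norms = load_utility_norms(),
                    B = 2000L, seed = 1L,
                    resample = c("within_arm", "pooled"),
                    drop_ward_outliers = FALSE) {
  resample <- match.arg(resample)
  cl <- match.call()
  if (!inherits(cohort, "pct_cohort")) {
    cohort <- structure(list(patients = cohort,
                             abx = if (is.null(abx)) data.frame(
                               patient_id = integer(0), name_text = character(0),
                               dose_text = character(0),
                               frequency_per_day = integer(0),
                               days = integer(0)) else abx,
                             params = NULL),
                        class = "pct_cohort")
  }
  qc <- apply_exclusions(cohort)
  clean <- qc$cohort
  outliers_removed <- NULL
  if (drop_ward_outliers) {
    clean <- remove_ward_outliers(clean, horizon = params$dt_horizon_days)
    outliers_removed <- attr(clean, "removed_by_arm")
  }
  p <- clean$patients

  costed <- cost_cohort_antibiotics(p, clean$abx, rules, prices, params)
  outcomes <- decision_tree_outcomes(p, costed, params, norms)
  coverage <- if (sum(costed$n_prescriptions) > 0) {
    sum(costed$n_matched) / sum(costed$n_prescriptions)
  } else 1

  # lifetime phase, memoized over attained integer age and sex
  alive <- outcomes$alive_at_1y
  age1 <- floor(outcomes$age) + 1L
  keyv <- paste(age1, outcomes$sex)
  mk <- unique(keyv[alive])
  mq <- vapply(mk, function(k) {
    parts <- strsplit(k, " ", fixed = TRUE)[[1]]
    markov_lifetime_qalys(as.numeric(parts[1]), parts[2], life_table, norms,
                          params)
  }, numeric(1))
  outcomes$qalys_markov <- ifelse(alive, mq[match(keyv, mk)], 0)
  outcomes$qalys_total <- outcomes$qalys_dt + outcomes$qalys_markov

  outcomes$died_in_hospital <- p$died_in_hospital
  outcomes$survival_days <- p$survival_days
  transitions <- estimate_transition_probabilities(outcomes,
                                                   params$dt_horizon_days)

  draws <- bootstrap_cea(outcomes, B = B, seed = seed, resample = resample,
                         params = params)
  summaries <- weighted_summary(outcomes, params, draws)

  pe <- function(stat, a) summaries$mean[summaries$arm == a &
                                           summaries$stat == stat]
  dE_dt <- pe("qalys_dt", "baseline_pct") - pe("qalys_dt", "no_baseline_pct")
  dE_total <- pe("qalys_total", "baseline_pct") -
    pe("qalys_total", "no_baseline_pct")
  dC <- pe("cost_total", "baseline_pct") - pe("cost_total", "no_baseline_pct")

  ceac_dt <- ceac(draws$dE_dt, draws$dC, params$threshold_grid)
  ceac_total <- ceac(draws$dE_total, draws$dC, params$threshold_grid)
  wtp <- params$wtp_threshold
  p_ce <- c(dt = mean(wtp * draws$dE_dt - draws$dC > 0),
            total = mean(wtp * draws$dE_total - draws$dC > 0))

  structure(list(
    call = cl,
    params = params,
    outcomes = outcomes,
    exclusion_log = qc$log,
    outliers_removed = outliers_removed,
    coverage_fraction = coverage,
    transitions = transitions,
    summaries = summaries,
    incremental = list(
      dt = list(dE = dE_dt, dC = dC, icer = icer(dE_dt, dC),
                icer_ci = stats::quantile(draws$dC / draws$dE_dt,
                                          c(0.025, 0.975), names = FALSE)),
      total = list(dE = dE_total, dC = dC, icer = icer(dE_total, dC),
                   icer_ci = stats::quantile(draws$dC / draws$dE_total,
                                             c(0.025, 0.975), names = FALSE))
    ),
    draws = draws,
    ceac = list(dt = ceac_dt, total = ceac_total),
    p_cost_effective = p_ce,
    B = B, seed = seed
  ), class = "pct_cea")
}
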