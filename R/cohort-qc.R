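#' Derive lengths of stay from raw day offsets
#'
#' Computes, for each patient, the total, ICU and general-ward lengths of
#' stay from raw admission/test/discharge day offsets. Total length of stay
#' is the days between the later of the positive COVID-19 test and hospital
#' admission, and discharge. ICU length of stay is the days between the later
#' of the positive test and ICU admission, and ICU discharge; a patient with
#' no ICU episode gets 0. General-ward days are total minus ICU days.
#' Missing inputs propagate as missing stays (missingness is data, not an
#' error); a negative derived total (discharge before admission) is treated
#' as a missing total stay.
#'
#' @param patients Data frame with columns `admission_day`, `covid_test_day`,
#'   `discharge_day`, `icu_in_day`, `icu_out_day` (integer day offsets,
#'   possibly `NA`).
#' @return The input with `total_days`, `icu_days` and `ward_days` columns
#'   appended (`NA` where underivable).
#' @examples
#' d <- data.frame(admission_day = 0, covid_test_day = 2, discharge_day = 10,
#'                 icu_in_day = NA, icu_out_day = NA)
#' derive_lengths_of_stay(d)[, c("total_days", "icu_days", "ward_days")]
#' @export
derive_lengths_of_stay <- function(patients) {
  start <- pmax(patients$admission_day, patients$covid_test_day)
  total <- patients$discharge_day - start
  total[!is.na(total) & total < 0] <- NA_real_
  no_icu <- is.na(patients$icu_in_day) & is.na(patients$icu_out_day)
  icu_start <- pmax(patients$covid_test_day, patients$icu_in_day)
  icu <- patients$icu_out_day - icu_start
  icu[no_icu] <- 0
  icu[!is.na(icu) & icu < 0] <- NA_real_
  patients$total_days <- as.numeric(total)
  patients$icu_days <- as.numeric(icu)
  patients$ward_days <- patients$total_days - patients$icu_days
  patients
}

.exclusion_rules <- c("missing_icu_los", "missing_total_los", "missing_survival",
                      "icu_gt_total", "total_gt_survival")

#' Apply the analysis exclusion rules
#'
#' Screens a cohort with derived lengths of stay and removes patients whose
#' records are unusable for the economic analysis: missing ICU length of
#' stay, missing total length of stay, missing survival time, an ICU stay
#' longer than the total stay, or a total stay longer than survival (records
#' failing the internal-consistency rules are assumed erroneous). Each
#' removed patient is attributed to the first rule they match, in that
#' listing order; because violations can overlap, an `any_match` count per
#' rule is reported alongside the first-match attribution.
#'
#' @param cohort A `pct_cohort`, or a patients data frame. Lengths of stay
#'   are derived first if absent.
#' @return A list of class `qc_result`: `cohort` (the cleaned cohort, ward
#'   days recomputed so every record satisfies
#'   `icu_days <= total_days <= survival_days`), and `log` (class
#'   `exclusion_log`) with `n_before`, `n_after`, per-rule `counts`
#'   (first-match) and `any_match`.
#' @examples
#' coh <- simulate_cohort(cohort_gen_params(n_patients = 100, seed = 3))
#' qc <- apply_exclusions(coh)
#' qc$log
#' @export
apply_exclusions <- function(cohort) {
  is_cohort <- inherits(cohort, "pct_cohort")
  p <- if (is_cohort) cohort$patients else cohort
  if (!"total_days" %in% names(p)) p <- derive_lengths_of_stay(p)
  n_before <- nrow(p)

  viol <- cbind(
    missing_icu_los = is.na(p$icu_days),
    missing_total_los = is.na(p$total_days),
    missing_survival = is.na(p$survival_days),
    icu_gt_total = !is.na(p$icu_days) & !is.na(p$total_days) &
      p$icu_days > p$total_days,
    total_gt_survival = !is.na(p$total_days) & !is.na(p$survival_days) &
      p$total_days > p$survival_days
  )
  first <- apply(viol, 1L, function(v) if (any(v)) which(v)[1L] else NA_integer_)
  keep <- is.na(first)
  counts <- vapply(seq_along(.exclusion_rules),
                   function(k) sum(first == k, na.rm = TRUE), integer(1))
  names(counts) <- .exclusion_rules
  any_match <- colSums(viol)

  clean <- p[keep, , drop = FALSE]
  clean$ward_days <- clean$total_days - clean$icu_days
  if (nrow(clean) == 0L)
    warning("all patients excluded; the cleaned cohort is empty", call. = FALSE)

  log <- structure(list(n_before = n_before, n_after = nrow(clean),
                        counts = counts, any_match = any_match),
                   class = "exclusion_log")
  if (is_cohort) {
    cohort$patients <- clean
    cohort$abx <- cohort$abx[cohort$abx$patient_id %in% clean$patient_id, ,
                             drop = FALSE]
    out <- cohort
  } else {
    out <- clean
  }
  structure(list(cohort = out, log = log), class = "qc_result")
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat(sprintf("Exclusions: %d of %d patients removed (%d retained)\n",
              x$n_before - x$n_after, x$n_before, x$n_after))
  for (r in names(x$counts)) {
    cat(sprintf("  %-18s first-match %4d   any-match %4d\n",
                r, x$counts[[r]], x$any_match[[r]]))
  }
  invisible(x)
}

#' @export
print.qc_result <- function(x, ...) {
  print(x$log)
  invisible(x)
}
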