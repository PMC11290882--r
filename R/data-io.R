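#' Read and write cohorts as CSV
#'
#' A cohort is stored as two plain CSV files: a patients table (one row per
#' patient, missing values as empty fields) and a companion long-format
#' antibiotic table keyed by `patient_id` (columns `name_text`, `dose_text`,
#' `frequency_per_day`, `days` and optionally `start_day`).
#'
#' @param cohort A `pct_cohort`.
#' @param patients_path,abx_path CSV file paths.
#' @return `read_cohort()` returns a `pct_cohort`; `write_cohort()` returns
#'   the paths, invisibly.
#' @name cohort_io
NULL

#' @rdname cohort_io
#' @export
write_cohort <- function(cohort, patients_path, abx_path) {
  utils::write.csv(cohort$patients, patients_path, row.names = FALSE,
                   na = "")
  utils::write.csv(cohort$abx, abx_path, row.names = FALSE, na = "")
  invisible(c(patients = patients_path, abx = abx_path))
}

#' @rdname cohort_io
#' @export
read_cohort <- function(patients_path, abx_path = NULL) {
  if (!file.exists(patients_path))
    stop("cohort file not found: '", patients_path, "'", call. = FALSE)
  p <- utils::read.csv(patients_path, stringsAsFactors = FALSE,
                       na.strings = "")
  if ("died_in_hospital" %in% names(p))
    p$died_in_hospital <- as.logical(p$died_in_hospital)
  abx <- if (!is.null(abx_path)) {
    if (!file.exists(abx_path))
      stop("antibiotic records file not found: '", abx_path, "'", call. = FALSE)
    utils::read.csv(abx_path, stringsAsFactors = FALSE, na.strings = "")
  } else {
    data.frame(patient_id = integer(0), name_text = character(0),
               dose_text = character(0), frequency_per_day = integer(0),
               days = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(patients = p, abx = abx, params = NULL),
            class = "pct_cohort")
}
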