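#' Bundled antibiotic resources
#'
#' The package ships three small plain-text resources used by the costing
#' pipeline: an ordered rule table mapping free-text antibiotic names to
#' canonical names (with a blocklist of common non-antibiotic drugs), a
#' synthetic two-tier unit-price table emulating the structure of the NHS
#' eMIT / BNF indicative price sources (the real extracts are versioned
#' external resources and are not shipped), and the canonical antibiotic
#' lexicon implied by the rules.
#'
#' @param path Path to a CSV in the documented dialect; defaults to the
#'   bundled file.
#' @return `load_abx_rules()`: a data frame with columns `pattern`,
#'   `canonical`, `action` (class `abx_rules`); `load_price_table()`: a data
#'   frame with columns `canonical_name`, `dose_value`, `dose_unit`,
#'   `unit_price`, `tier` (class `price_table`); `abx_lexicon()`: a character
#'   vector of canonical names.
#' @name abx_resources
NULL

#' @rdname abx_resources
#' @export
load_abx_rules <- function(path = system.file("extdata", "abx_rules.csv",
                                              package = "pctcea")) {
  if (!nzchar(path) || !file.exists(path))
    stop("antibiotic rules file not found: '", path, "'", call. = FALSE)
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pattern", "canonical", "action")
  if (!all(need %in% names(r)))
    stop("rules file must have columns pattern, canonical, action", call. = FALSE)
  if (!all(r$action %in% c("map", "block")))
    stop("rules file: action must be 'map' or 'block'", call. = FALSE)
  can <- unique(r$canonical[r$action == "map"])
  if (any(!nzchar(can)))
    stop("rules file: every 'map' rule needs a canonical name", call. = FALSE)
  structure(r, class = c("abx_rules", "data.frame"))
}

#' @rdname abx_resources
#' @export
abx_lexicon <- function(path = system.file("extdata", "abx_rules.csv",
                                           package = "pctcea")) {
  r <- load_abx_rules(path)
  sort(unique(r$canonical[r$action == "map"]))
}

#' @rdname abx_resources
#' @export
load_price_table <- function(path = system.file("extdata",
                                                "abx_prices_synthetic.csv",
                                                package = "pctcea")) {
  if (!nzchar(path) || !file.exists(path))
    stop("price table file not found: '", path, "'", call. = FALSE)
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("canonical_name", "dose_value", "dose_unit", "unit_price", "tier")
  if (!all(need %in% names(p)))
    stop("price table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  if (any(p$unit_price < 0)) stop("price table: unit_price must be >= 0", call. = FALSE)
  if (!all(p$tier %in% c("primary", "indicative")))
    stop("price table: tier must be 'primary' or 'indicative'", call. = FALSE)
  key <- paste(p$canonical_name, p$dose_value, p$dose_unit, p$tier)
  if (anyDuplicated(key))
    stop("price table: (name, dose, unit, tier) entries must be unique", call. = FALSE)
  structure(p, class = c("price_table", "data.frame"))
}

# lowercase, trim, collapse internal whitespace, drop trailing punctuation
clean_abx_text <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[[:space:]]+", " ", x)
  sub("[.,;:]+$", "", x)
}

#' Normalize a free-text antibiotic name
#'
#' Maps messy free-text drug names (misspellings, shorthand such as
#' "pip-taz", case and whitespace variants) onto a canonical antibiotic name.
#' Matching proceeds in order: cleaning (case, whitespace), blocklist of
#' known non-antibiotics, exact lexicon match, the ordered regular-expression
#' rules (first match wins), a unique-prefix match of at least 5 characters,
#' and finally a single-edit fuzzy match against the lexicon. Text that
#' matches nothing is returned as `"unrecognized"`; blocklisted drugs return
#' `"non_antibiotic"`.
#'
#' @param raw Character vector of free-text names.
#' @param rules An `abx_rules` table from [load_abx_rules()].
#' @return Character vector: a canonical name, `"non_antibiotic"`, or
#'   `"unrecognized"` per element.
#' @examples
#' rules <- load_abx_rules()
#' normalize_abx_name(c("AMOXICILLIN ", "pip-taz", "paracetamol"), rules)
#' @export
normalize_abx_name <- function(raw, rules = load_abx_rules()) {
  lex <- sort(unique(rules$canonical[rules$action == "map"]))
  block_pat <- rules$pattern[rules$action == "block"]
  map_idx <- which(rules$action == "map")
  vapply(as.character(raw), function(x) {
    x <- clean_abx_text(x)
    if (!nzchar(x)) return("unrecognized")
    for (bp in block_pat) {
      if (grepl(bp, x, ignore.case = TRUE)) return("non_antibiotic")
    }
    if (x %in% lex) return(x)
    for (i in map_idx) {
      if (grepl(rules$pattern[i], x, ignore.case = TRUE)) return(rules$canonical[i])
    }
    if (nchar(x) >= 5) {
      hit <- lex[startsWith(lex, x)]
      if (length(hit) == 1L) return(hit)
    }
    d <- utils::adist(x, lex)
    near <- which(d == 1L)
    if (length(near) == 1L) return(lex[near])
    "unrecognized"
  }, character(1), USE.NAMES = FALSE)
}

# canonical dose units and their synonyms
.dose_units <- list(
  mg    = c("mg", "mgs", "milligram", "milligrams", "mgram"),
  g     = c("g", "gr", "gram", "grams", "gm"),
  mL    = c("ml", "mls", "millilitre", "millilitres", "milliliter",
            "milliliters", "cc"),
  units = c("unit", "units", "iu", "u", "international units")
)

#' Parse a free-text dose string
#'
#' Recognizes a numeric value followed by a dose unit, accepting unit
#' synonyms ("500 millilitres" is read as 500 mL). Masses given in grams are
#' converted to milligrams so doses are comparable with price-table entries.
#'
#' @param raw Character vector of dose strings.
#' @return A data frame with columns `value`, `unit` and `parsed`; unparsed
#'   entries have `parsed = FALSE` and `NA` value/unit.
#' @examples
#' parse_dose(c("500 millilitres", "1 g", "one tablet"))
#' @export
parse_dose <- function(raw) {
  out <- data.frame(value = rep(NA_real_, length(raw)),
                    unit = rep(NA_character_, length(raw)),
                    parsed = rep(FALSE, length(raw)),
                    stringsAsFactors = FALSE)
  syn <- stats::setNames(rep(names(.dose_units), lengths(.dose_units)),
                         unlist(.dose_units))
  m <- regmatches(raw, regexec("([0-9]+(?:[.][0-9]+)?)[[:space:]]*([a-zA-Z ]+)",
                               tolower(trimws(as.character(raw))), perl = TRUE))
  for (i in seq_along(raw)) {
    if (length(m[[i]]) != 3L) next
    val <- as.numeric(m[[i]][2])
    u <- trimws(m[[i]][3])
    if (!u %in% names(syn)) u <- strsplit(u, " ", fixed = TRUE)[[1]][1]
    if (!u %in% names(syn)) next
    unit <- unname(syn[[u]])
    if (unit == "g") { val <- val * 1000; unit <- "mg" }
    out$value[i] <- val
    out$unit[i] <- unit
    out$parsed[i] <- TRUE
  }
  out
}

#' Match a dose to the two-tier price table
#'
#' Looks a canonical drug name and parsed dose up in the price table,
#' preferring the primary tier (eMIT-style actual purchase prices) over the
#' indicative tier (BNF-style list prices). Within a tier an exact dose match
#' is preferred; otherwise the prescribed dose may be assembled as the
#' smallest integer multiple k >= 2 of an available dose, costing k times the
#' unit price (ties broken by the lowest resulting cost).
#'
#' @param name Canonical antibiotic name.
#' @param dose_value,dose_unit Parsed dose (see [parse_dose()]).
#' @param table A `price_table` from [load_price_table()].
#' @return A list with `matched` (logical), and when matched `per_dose_cost`,
#'   `tier` and `multiple` (1 for an exact match).
#' @export
match_price <- function(name, dose_value, dose_unit, table = load_price_table()) {
  unmatched <- list(matched = FALSE, per_dose_cost = NA_real_,
                    tier = NA_character_, multiple = NA_integer_)
  if (is.na(name) || is.na(dose_value) || is.na(dose_unit)) return(unmatched)
  for (tier in c("primary", "indicative")) {
    e <- table[table$canonical_name == name & table$tier == tier &
                 table$dose_unit == dose_unit, , drop = FALSE]
    if (nrow(e) == 0L) next
    exact <- e[e$dose_value == dose_value, , drop = FALSE]
    if (nrow(exact) > 0L) {
      j <- which.min(exact$unit_price)
      return(list(matched = TRUE, per_dose_cost = exact$unit_price[j],
                  tier = tier, multiple = 1L))
    }
    k <- dose_value / e$dose_value
    ok <- which(abs(k - round(k)) < 1e-9 & round(k) >= 2)
    if (length(ok) > 0L) {
      kk <- as.integer(round(k[ok]))
      cost <- kk * e$unit_price[ok]
      j <- order(kk, cost)[1L]  # smallest multiple, then cheapest
      return(list(matched = TRUE, per_dose_cost = cost[j], tier = tier,
                  multiple = kk[j]))
    }
  }
  unmatched
}

#' Cost a patient's antibiotic records
#'
#' Normalizes each record's name, parses its dose, matches it to the price
#' table, and totals drug and antimicrobial-resistance (AMR) costs. The drug
#' cost of a matched record is its per-dose cost times doses per day times
#' days of treatment. The AMR surcharge is applied per prescription (one
#' record = one prescription) by default, or per dose when
#' `params$amr_unit == "per_dose"`. Antibiotic days are counted as calendar
#' days on at least one antibiotic: when records carry a `start_day` the
#' union of their day ranges is used, otherwise courses are assumed
#' sequential and days are summed.
#'
#' @param records Data frame of antibiotic records with columns `name_text`,
#'   `dose_text`, `frequency_per_day`, `days` and optionally `start_day`.
#' @param rules,table Normalization rules and price table.
#' @param params An [econ_params()] object (AMR unit cost and unit).
#' @return A list: `total_drug_cost`, `amr_cost`, `coverage_fraction`
#'   (matched / antibiotic records; 1 when there are no antibiotic records),
#'   `abx_days`, `n_prescriptions`, and a per-record data frame `detail`.
#' @examples
#' recs <- data.frame(name_text = "Amoxicillin", dose_text = "500 mg",
#'                    frequency_per_day = 3, days = 5)
#' cost_antibiotics(recs)$total_drug_cost
#' @export
cost_antibiotics <- function(records, rules = load_abx_rules(),
                             table = load_price_table(),
                             params = econ_params()) {
  empty <- list(total_drug_cost = 0, amr_cost = 0, coverage_fraction = 1,
                abx_days = 0, n_prescriptions = 0L, detail = NULL)
  if (is.null(records) || nrow(records) == 0L) return(empty)
  canon <- normalize_abx_name(records$name_text, rules)
  dose <- parse_dose(records$dose_text)
  is_abx <- canon != "non_antibiotic"
  n_abx <- sum(is_abx)
  if (n_abx == 0L) return(empty)
  per_dose <- rep(NA_real_, nrow(records))
  tier <- rep(NA_character_, nrow(records))
  matched <- rep(FALSE, nrow(records))
  for (i in which(is_abx & !canon %in% "unrecognized")) {
    m <- match_price(canon[i], dose$value[i], dose$unit[i], table)
    matched[i] <- m$matched
    per_dose[i] <- m$per_dose_cost
    tier[i] <- m$tier
  }
  freq <- records$frequency_per_day
  days <- records$days
  rec_cost <- ifelse(matched, per_dose * freq * days, 0)
  n_doses <- sum(freq[is_abx] * days[is_abx])
  amr_cost <- if (params$amr_unit == "per_dose") {
    params$c_amr_per_prescription * n_doses
  } else {
    params$c_amr_per_prescription * n_abx
  }
  abx <- records[is_abx, , drop = FALSE]
  if (!is.null(abx$start_day) && !anyNA(abx$start_day)) {
    cov <- unique(unlist(Map(function(s, d) if (d > 0) seq.int(s, s + d - 1L) else integer(0),
                             abx$start_day, abx$days)))
    abx_days <- length(cov)
  } else {
    abx_days <- sum(abx$days)
  }
  list(total_drug_cost = sum(rec_cost),
       amr_cost = amr_cost,
       coverage_fraction = sum(matched & is_abx) / n_abx,
       abx_days = abx_days,
       n_prescriptions = n_abx,
       detail = data.frame(name_text = records$name_text, canonical = canon,
                           matched = matched, per_dose_cost = per_dose,
                           tier = tier, record_cost = rec_cost,
                           stringsAsFactors = FALSE))
}
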