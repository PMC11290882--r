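#' Display rounding conventions
#'
#' Rounds a value the way the report tables display it: probabilities and
#' QALY losses to 3 significant figures; costs to 3 significant figures
#' below GBP 1000 and to the nearest GBP 10 at or above GBP 1000.
#'
#' @param x Numeric vector.
#' @param type `"probability"`, `"qaly"` or `"cost"`.
#' @return Rounded numeric vector.
#' @examples
#' display_round(0.0091466, "qaly")   # 0.00915
#' display_round(6084.3, "cost")      # 6080
#' display_round(0.3091, "probability")
#' @export
display_round <- function(x, type = c("probability", "qaly", "cost")) {
  type <- match.arg(type)
  if (type == "cost") {
    ifelse(!is.na(x) & abs(x) >= 1000, round(x / 10) * 10, signif(x, 3))
  } else {
    signif(x, 3)
  }
}

#' Render report tables from a fitted model
#'
#' Produces the CSV-ready tables the pipeline emits: decision-tree
#' transition probabilities; per-component days, QALY losses and costs by
#' arm; and the headline survival/QALY/cost/ICER table. Display rounding
#' follows [display_round()].
#'
#' @param fit A `pct_cea` fit.
#' @return A named list of data frames: `transitions`, `components`,
#'   `headline`, `ce_plane`, `ceac`.
#' @export
render_tables <- function(fit) {
  s <- fit$summaries
  get3 <- function(stat, a) {
    r <- s[s$stat == stat & s$arm == a, , drop = FALSE]
    if (nrow(r) == 0L) return(c(NA_real_, NA_real_, NA_real_))
    c(r$mean, r$lo, r$hi)
  }
  comp_map <- data.frame(
    component = c("general_ward_days", "icu_days", "pct_tests",
                  "antibiotic_days", "amr"),
    days = c("ward_days", "icu_days", "pct_tests", "abx_days", NA),
    qloss = c("qloss_ward", "qloss_icu", NA, "qloss_abx", NA),
    cost = c("cost_ward", "cost_icu", "cost_pct", "cost_drugs", "cost_amr"),
    stringsAsFactors = FALSE
  )
  rows <- list()
  for (a in c("baseline_pct", "no_baseline_pct")) {
    for (i in seq_len(nrow(comp_map))) {
      dd <- if (is.na(comp_map$days[i])) rep(NA_real_, 3) else
        signif(get3(comp_map$days[i], a), 3)
      qq <- if (is.na(comp_map$qloss[i])) rep(NA_real_, 3) else
        display_round(get3(comp_map$qloss[i], a), "qaly")
      cc <- display_round(get3(comp_map$cost[i], a), "cost")
      rows[[length(rows) + 1L]] <- data.frame(
        arm = a, component = comp_map$component[i],
        mean = dd[1], lo = dd[2], hi = dd[3],
        qaly_loss = qq[1], qaly_loss_lo = qq[2], qaly_loss_hi = qq[3],
        cost = cc[1], cost_lo = cc[2], cost_hi = cc[3],
        stringsAsFactors = FALSE
      )
    }
  }
  components <- do.call(rbind, rows)

  head_stats <- c(survival_capped = "qaly", p_1y_survival = "probability",
                  baseline_utility = "probability", qalys_dt = "qaly",
                  qalys_total = "qaly", cost_total = "cost")
  rows <- list()
  for (a in c("baseline_pct", "no_baseline_pct")) {
    for (st in names(head_stats)) {
      v <- get3(st, a)
      v <- display_round(v, head_stats[[st]])
      rows[[length(rows) + 1L]] <- data.frame(
        arm = a, stat = st, mean = v[1], lo = v[2], hi = v[3],
        stringsAsFactors = FALSE)
    }
  }
  inc <- fit$incremental
  rows[[length(rows) + 1L]] <- data.frame(
    arm = "incremental", stat = "icer_dt",
    mean = display_round(inc$dt$icer$icer, "cost"),
    lo = display_round(inc$dt$icer_ci[1], "cost"),
    hi = display_round(inc$dt$icer_ci[2], "cost"), stringsAsFactors = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    arm = "incremental", stat = "icer_total",
    mean = display_round(inc$total$icer$icer, "cost"),
    lo = display_round(inc$total$icer_ci[1], "cost"),
    hi = display_round(inc$total$icer_ci[2], "cost"), stringsAsFactors = FALSE)
  headline <- do.call(rbind, rows)

  trans <- fit$transitions
  trans$probability <- display_round(trans$probability, "probability")

  ce_plane <- data.frame(
    iteration = seq_along(fit$draws$dC),
    dE_dt = fit$draws$dE_dt, dE_total = fit$draws$dE_total, dC = fit$draws$dC)
  ceac_tab <- rbind(
    data.frame(horizon = "decision_tree", fit$ceac$dt),
    data.frame(horizon = "lifetime", fit$ceac$total))

  list(transitions = trans, components = components, headline = headline,
       ce_plane = ce_plane, ceac = ceac_tab)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/ingest, cleaning, antibiotic costing, the economic
#' model, the bootstrap and table emission, writing every output plus a
#' machine-readable run manifest to an output directory. Configuration is a
#' YAML file or an equivalent named list; every source of randomness flows
#' from a single root seed split per stage. With `robustness: true` the
#' analysis is repeated after removing full-year general-ward outliers and
#' `*_robust.csv` outputs are written alongside.
#'
#' Config fields (all optional unless noted): `out_dir` (required), `seed`,
#' `n_patients`, `bootstrap_iterations`, `robustness`, `cohort_csv` +
#' `abx_csv` (ingest instead of simulating), `price_table`, `rules`,
#' `life_table`, `utility_norms` (resource paths), `cohort` (overrides for
#' [cohort_gen_params()]) and `econ` (overrides for [econ_params()]).
#'
#' @param config Path to a YAML config, or a named list.
#' @param seed Overrides the config seed when not `NULL`.
#' @return The output directory path, invisibly; the fitted `pct_cea` object
#'   is attached as attribute `fit`.
#' @export
run_pipeline <- function(config, seed = NULL) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: '", config, "'", call. = FALSE)
    yaml::read_yaml(config)
  } else {
    config
  }
  if (is.null(cfg$out_dir)) stop("config must name 'out_dir'", call. = FALSE)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  root_seed <- as.integer(if (!is.null(seed)) seed else
    if (!is.null(cfg$seed)) cfg$seed else 1L)
  set.seed(root_seed)
  stage_seed <- sample.int(.Machine$integer.max - 1L, 2L)

  for (f in c("price_table", "rules", "life_table", "utility_norms")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("config: ", f, " path not found: '", cfg[[f]], "'", call. = FALSE)
  }
  rules <- if (is.null(cfg$rules)) load_abx_rules() else load_abx_rules(cfg$rules)
  prices <- if (is.null(cfg$price_table)) load_price_table() else
    load_price_table(cfg$price_table)
  life_table <- if (is.null(cfg$life_table)) load_life_table() else
    load_life_table(cfg$life_table)
  norms <- if (is.null(cfg$utility_norms)) load_utility_norms() else
    load_utility_norms(cfg$utility_norms)

  if (!is.null(cfg$cohort_csv)) {
    cohort <- read_cohort(cfg$cohort_csv, cfg$abx_csv)
    gen_params <- NULL
  } else {
    gp <- cfg$cohort
    if (is.null(gp)) gp <- list()
    if (!is.null(cfg$n_patients)) gp$n_patients <- cfg$n_patients
    gp$seed <- stage_seed[1L]
    gen_params <- do.call(cohort_gen_params, gp)
    cohort <- simulate_cohort(gen_params)
  }
  params <- do.call(econ_params, if (is.null(cfg$econ)) list() else cfg$econ)
  B <- if (is.null(cfg$bootstrap_iterations)) 2000L else
    as.integer(cfg$bootstrap_iterations)

  fit <- pct_cea(cohort, params = params, rules = rules, prices = prices,
                 life_table = life_table, norms = norms, B = B,
                 seed = stage_seed[2L])
  write_outputs(fit, out_dir, suffix = "")

  if (isTRUE(cfg$robustness)) {
    fit_r <- pct_cea(cohort, params = params, rules = rules, prices = prices,
                     life_table = life_table, norms = norms, B = B,
                     seed = stage_seed[2L], drop_ward_outliers = TRUE)
    write_outputs(fit_r, out_dir, suffix = "_robust")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("pctcea")),
    root_seed = root_seed,
    stage_seeds = list(simulate = stage_seed[1L], bootstrap = stage_seed[2L]),
    bootstrap_iterations = B,
    n_patients = nrow(cohort$patients),
    generator = if (is.null(gen_params)) NULL else unclass(gen_params),
    econ_params = unclass(params),
    resources = list(
      rules = if (is.null(cfg$rules)) "bundled" else cfg$rules,
      price_table = if (is.null(cfg$price_table)) "bundled" else cfg$price_table,
      life_table = if (is.null(cfg$life_table)) "bundled" else cfg$life_table,
      utility_norms = if (is.null(cfg$utility_norms)) "bundled" else
        cfg$utility_norms),
    robustness = isTRUE(cfg$robustness)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  log_lines <- c(
    sprintf("patients before exclusions: %d", fit$exclusion_log$n_before),
    sprintf("patients after exclusions:  %d", fit$exclusion_log$n_after),
    vapply(names(fit$exclusion_log$counts), function(r)
      sprintf("  excluded (%s): %d", r, fit$exclusion_log$counts[[r]]),
      character(1)),
    sprintf("antibiotic costing coverage: %.3f", fit$coverage_fraction),
    sprintf("P(cost-effective) 1-year: %.3f, lifetime: %.3f",
            fit$p_cost_effective[["dt"]], fit$p_cost_effective[["total"]]))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  out <- out_dir
  attr(out, "fit") <- fit
  invisible(out)
}

write_outputs <- function(fit, out_dir, suffix = "") {
  tabs <- render_tables(fit)
  wr <- function(d, name) {
    utils::write.csv(d, file.path(out_dir, paste0(name, suffix, ".csv")),
                     row.names = FALSE, na = "")
  }
  wr(tabs$transitions, "transition_table3")
  wr(tabs$components, "summary_table4")
  wr(tabs$headline, "summary_table5")
  wr(tabs$ce_plane, "ce_plane_draws")
  wr(tabs$ceac, "ceac")
  el <- fit$exclusion_log
  wr(data.frame(rule = names(el$counts), first_match = unname(el$counts),
                any_match = unname(el$any_match)), "exclusion_log")
  invisible(NULL)
}
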