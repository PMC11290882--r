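#' @export
print.pct_cea <- function(x, ...) {
  cat("Cost-effectiveness of baseline procalcitonin testing\n")
  cat(sprintf("  %d patients after exclusions (%d removed); antibiotic costing coverage %.1f%%\n",
              x$exclusion_log$n_after,
              x$exclusion_log$n_before - x$exclusion_log$n_after,
              100 * x$coverage_fraction))
  inc <- x$incremental
  cat(sprintf("  Decision-tree horizon:  dQALY %+.4f, dCost GBP %+.0f, ICER %s (%s)\n",
              inc$dt$dE, inc$dt$dC, fmt_icer(inc$dt$icer), inc$dt$icer$quadrant))
  cat(sprintf("  Lifetime horizon:       dQALY %+.4f, dCost GBP %+.0f, ICER %s (%s)\n",
              inc$total$dE, inc$total$dC, fmt_icer(inc$total$icer),
              inc$total$icer$quadrant))
  cat(sprintf("  P(cost-effective at GBP %s/QALY): %.3f (1-year), %.3f (lifetime); B = %d\n",
              format(x$params$wtp_threshold, big.mark = " "),
              x$p_cost_effective[["dt"]], x$p_cost_effective[["total"]], x$B))
  invisible(x)
}

fmt_icer <- function(ic) {
  if (isTRUE(ic$undefined)) "undefined (dQALY = 0)"
  else sprintf("GBP %.0f/QALY", ic$icer)
}

#' Summarize a fitted cost-effectiveness model
#'
#' @param object A `pct_cea` fit.
#' @param ... Unused.
#' @return A list of class `summary.pct_cea` with the per-arm weighted
#'   summary table (with bootstrap CIs), transition probabilities,
#'   incremental results and headline cost-effectiveness probabilities.
#' @export
summary.pct_cea <- function(object, ...) {
  structure(list(
    summaries = object$summaries,
    transitions = object$transitions,
    incremental = object$incremental,
    p_cost_effective = object$p_cost_effective,
    exclusion_log = object$exclusion_log,
    coverage_fraction = object$coverage_fraction,
    B = object$B
  ), class = "summary.pct_cea")
}

#' @export
print.summary.pct_cea <- function(x, ...) {
  cat("Per-arm weighted means (95% bootstrap CI)\n")
  s <- x$summaries
  for (a in unique(s$arm)) {
    cat(" ", a, "\n")
    d <- s[s$arm == a, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      cat(sprintf("    %-17s %12.4g", d$stat[i], d$mean[i]))
      if (!is.null(d$lo)) cat(sprintf("  (%.4g, %.4g)", d$lo[i], d$hi[i]))
      cat("\n")
    }
  }
  cat("Decision-tree transition probabilities\n")
  print(x$transitions, row.names = FALSE)
  cat(sprintf("P(cost-effective): %.3f (1-year), %.3f (lifetime)\n",
              x$p_cost_effective[["dt"]], x$p_cost_effective[["total"]]))
  invisible(x)
}

#' Incremental estimates of a fitted model
#'
#' @param object A `pct_cea` fit.
#' @param ... Unused.
#' @return Named vector: incremental QALYs (both horizons), incremental cost,
#'   and the two ICERs.
#' @export
coef.pct_cea <- function(object, ...) {
  inc <- object$incremental
  c(dE_dt = inc$dt$dE, dE_total = inc$total$dE, dC = inc$dt$dC,
    icer_dt = inc$dt$icer$icer, icer_total = inc$total$icer$icer)
}

#' Plot a fitted cost-effectiveness model
#'
#' Draws the cost-effectiveness plane (bootstrap draws of incremental QALYs
#' and costs) and the cost-effectiveness acceptability curves for the
#' one-year and lifetime horizons.
#'
#' @param x A `pct_cea` fit.
#' @param which `"plane"`, `"ceac"` or both.
#' @param max_points Cap on plotted plane draws.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.pct_cea <- function(x, which = c("plane", "ceac"), max_points = 5000L,
                         ...) {
  which <- match.arg(which, several.ok = TRUE)
  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old), add = TRUE)
  if (length(which) == 2L) graphics::par(mfrow = c(1, 2))
  if ("plane" %in% which) {
    i <- seq_len(min(max_points, length(x$draws$dC)))
    rng_e <- range(x$draws$dE_dt[i], x$draws$dE_total[i])
    graphics::plot(x$draws$dE_total[i], x$draws$dC[i],
                   pch = 16, cex = 0.3, col = grDevices::adjustcolor("steelblue", 0.4),
                   xlim = rng_e,
                   xlab = "Incremental QALYs", ylab = "Incremental cost (GBP)",
                   main = "Cost-effectiveness plane", ...)
    graphics::points(x$draws$dE_dt[i], x$draws$dC[i], pch = 16, cex = 0.3,
                     col = grDevices::adjustcolor("tomato", 0.4))
    graphics::abline(h = 0, v = 0, lty = 3)
    graphics::legend("topleft", pch = 16, col = c("tomato", "steelblue"),
                     legend = c("1-year horizon", "lifetime horizon"),
                     bty = "n", cex = 0.8)
  }
  if ("ceac" %in% which) {
    graphics::plot(x$ceac$total$threshold, x$ceac$total$p_cost_effective,
                   type = "l", ylim = c(0, 1), col = "steelblue", lwd = 2,
                   xlab = "Willingness to pay (GBP/QALY)",
                   ylab = "P(cost-effective)",
                   main = "Acceptability curves", ...)
    graphics::lines(x$ceac$dt$threshold, x$ceac$dt$p_cost_effective,
                    col = "tomato", lwd = 2)
    graphics::abline(v = x$params$wtp_threshold, lty = 3)
    graphics::legend("bottomright", lwd = 2, col = c("tomato", "steelblue"),
                     legend = c("1-year horizon", "lifetime horizon"),
                     bty = "n", cex = 0.8)
  }
  invisible(x)
}
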