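classify_dominance <- function(delta_cost, delta_qaly) {
  sc <- sign(delta_cost)
  se <- sign(delta_qaly)
  if (sc == 0 && se == 0) return("equal")
  if (sc <= 0 && se >= 0) return("dominant")
  if (sc >= 0 && se <= 0) return("dominated")
  "icer"
}

#' Pairwise cost-effectiveness comparison
#'
#' Computes incremental cost and incremental QALYs of an intervention over a
#' comparator and classifies the pair: `dominant` (costs less, yields at
#' least as much effect, with at least one margin strict), `dominated` (the
#' mirror image), `equal` (both margins zero), or `icer` when a genuine
#' trade-off exists, in which case the incremental cost-effectiveness ratio
#' `delta_cost / delta_qaly` is reported. The ICER is computed from
#' full-precision model outputs; rounding is left to the reporting layer.
#'
#' @param intervention,comparator `strategy_result` objects from the same
#'   parameter set and population.
#' @return An object of class `cea_comparison`: list with `intervention`,
#'   `comparator`, `delta_cost_jpy`, `delta_qaly`, `icer_jpy_per_qaly`
#'   (`NA` unless `label == "icer"`), `label`.
#' @export
compare_strategies <- function(intervention, comparator) {
  stopifnot(inherits(intervention, "strategy_result"),
            inherits(comparator, "strategy_result"))
  if (!identical(intervention$age_group, comparator$age_group)) {
    stop("comparison requires results for the same population", call. = FALSE)
  }
  dc <- intervention$expected_cost_jpy - comparator$expected_cost_jpy
  de <- intervention$expected_qaly - comparator$expected_qaly
  label <- classify_dominance(dc, de)
  structure(list(intervention = intervention$strategy,
                 comparator = comparator$strategy,
                 delta_cost_jpy = dc, delta_qaly = de,
                 icer_jpy_per_qaly = if (label == "icer") dc / de else NA_real_,
                 label = label),
            class = "cea_comparison")
}

#' @export
print.cea_comparison <- function(x, ...) {
  icer <- if (x$label == "icer") {
    sprintf(", ICER JPY %.0f/QALY", x$icer_jpy_per_qaly)
  } else ""
  cat(sprintf("<cea_comparison> %s vs %s: dCost JPY %.0f, dQALY %.5f [%s%s]\n",
              x$intervention, x$comparator, x$delta_cost_jpy, x$delta_qaly,
              x$label, icer))
  invisible(x)
}

#' Net monetary benefit of a comparison
#'
#' `NMB = wtp * delta_qaly - delta_cost`; the intervention is cost-effective
#' at the willingness-to-pay threshold exactly when the NMB is positive.
#' Linear in the threshold with slope `delta_qaly`, so dominant comparisons
#' have positive NMB at every positive threshold.
#'
#' @param comparison A [compare_strategies()] result, or any list with
#'   `delta_cost_jpy` and `delta_qaly`.
#' @param wtp Willingness to pay (JPY per QALY, > 0).
#' @return The net monetary benefit in JPY.
#' @export
net_monetary_benefit <- function(comparison, wtp) {
  stopifnot(is.numeric(wtp), wtp > 0)
  wtp * comparison$delta_qaly - comparison$delta_cost_jpy
}

#' Convert JPY to whole US dollars
#'
#' Divides by the configured exchange rate and rounds half-up to the nearest
#' integer (matching conventional currency reporting, not banker's
#' rounding).
#'
#' @param amount_jpy Amount in JPY.
#' @param jpy_per_usd Exchange rate (> 0), e.g. 107.
#' @return Integer USD amount.
#' @export
jpy_to_usd <- function(amount_jpy, jpy_per_usd) {
  stopifnot(is.numeric(jpy_per_usd), jpy_per_usd > 0)
  x <- amount_jpy / jpy_per_usd
  sign(x) * floor(abs(x) + 0.5)
}

#' Base-case comparison set
#'
#' The three comparisons of interest: the intervention versus each other
#' strategy.
#'
#' @param results A `strategy_results` list from [evaluate_all()].
#' @param intervention Strategy compared against the rest (default
#'   `"lemborexant"`).
#' @return Named list of `cea_comparison` objects.
#' @export
compare_all <- function(results, intervention = "lemborexant") {
  stopifnot(inherits(results, "strategy_results"))
  comparators <- setdiff(strategies(), intervention)
  out <- lapply(comparators, function(s) {
    compare_strategies(results[[intervention]], results[[s]])
  })
  names(out) <- comparators
  out
}

#' @export
as.data.frame.cea_comparison <- function(x, ...) {
  data.frame(intervention = x$intervention, comparator = x$comparator,
             delta_cost_jpy = x$delta_cost_jpy, delta_qaly = x$delta_qaly,
             icer_jpy_per_qaly = x$icer_jpy_per_qaly, label = x$label,
             row.names = NULL)
}
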