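#' Evaluate one strategy of the decision tree
#'
#' Accrues expected quality-adjusted life years (QALYs) and expected direct
#' medical cost (JPY) over the model horizon for one strategy, either within
#' one age stratum or as the population-weighted mix of the two strata.
#'
#' QALYs start from the general-population utility norm over the horizon
#' (responders are assumed to regain good-sleeper utility); non-responders
#' lose the chronic-insomnia utility decrement for the whole horizon; each
#' expected adverse event subtracts a one-off, duration-integrated
#' disutility (falls are weighted over the care/fracture split, with
#' non-fracture admissions conservatively carrying the plain fall
#' disutility and workplace accidents carrying none); deaths forfeit half a
#' horizon of norm utility (midpoint timing).
#'
#' Costs accrue drug cost per day over 365.25 x horizon days and physician
#' visits per month over 12 x horizon months -- both zero for untreated
#' insomnia, and both pro-rated to the horizon midpoint for decedents --
#' plus per-event treatment costs (falls: care-level costs over the outcome
#' split times the expected number of falls; collisions and workplace
#' accidents: a flat unit cost per event).
#'
#' @param strategy One of [strategies()].
#' @param age_group One of [age_groups()], or `"mixed"` for the
#'   population-weighted combination.
#' @param params A validated [parameter_set()].
#' @return An object of class `strategy_result`: list with `strategy`,
#'   `age_group`, `expected_cost_jpy`, `expected_qaly`, `death_probability`,
#'   and named breakdowns `cost_breakdown` (drug, visits, fall, mvc, wpa)
#'   and `qaly_breakdown` (baseline, insomnia, fall, mvc, wpa, death).
#' @export
evaluate_strategy <- function(strategy, age_group = "mixed", params) {
  stopifnot(inherits(params, "parameter_set"))
  strategy <- match.arg(strategy, strategies())
  if (age_group == "mixed") {
    w <- params$values[c("age_weight.younger", "age_weight.older")]
    parts <- lapply(age_groups(), evaluate_strategy_age,
                    strategy = strategy, params = params)
    return(mix_results(parts, unname(w), "mixed"))
  }
  evaluate_strategy_age(strategy, match.arg(age_group, age_groups()), params)
}

evaluate_strategy_age <- function(strategy, age_group, params) {
  v <- params$values
  T <- v[["horizon_years"]]
  u <- v[["utility_norm"]]
  r <- v[[paste0("response_rate.", strategy)]]

  risks <- lapply(events(), event_risk, strategy = strategy,
                  age_group = age_group, params = params)
  names(risks) <- events()
  death <- sum(vapply(risks, `[[`, 0, "death_probability"))

  split <- fall_split_from_values(v)
  # per-fall expected disutility and cost over the care/fracture cascade;
  # non-fracture admissions reuse the plain fall disutility
  fall_du <- (split[["p_no_care"]] + split[["p_outpatient"]] +
                split[["p_admit_nonfracture"]]) * v[["disutility.fall"]] +
    split[["p_admit_nonhip_fracture"]] * v[["disutility.fracture_nonhip"]] +
    split[["p_admit_hip_fracture"]] * v[["disutility.fracture_hip"]]
  fall_cost <- split[["p_outpatient"]] * v[["cost.fall_outpatient"]] +
    split[["p_admit_nonfracture"]] * v[["cost.fall_admit_nonfracture"]] +
    split[["p_admit_nonhip_fracture"]] * v[["cost.fall_admit_nonhip_fracture"]] +
    split[["p_admit_hip_fracture"]] * v[["cost.fall_admit_hip_fracture"]]

  event_du <- c(fall = fall_du, mvc = v[["disutility.mvc"]],
                wpa = v[["disutility.wpa"]])
  event_cost <- c(fall = fall_cost, mvc = v[["cost.mvc"]],
                  wpa = v[["cost.wpa"]])
  counts <- vapply(risks, `[[`, 0, "expected_count_per_capita")

  qaly_breakdown <- c(
    baseline = u * T,
    insomnia = -(1 - r) * v[["insomnia_disutility"]] * T,
    -counts * event_du,
    death = -death * u * T / 2)
  qaly <- sum(qaly_breakdown)
  if (qaly < 0) {
    warning("expected QALY ", signif(qaly, 4), " for ", strategy, "/",
            age_group, " floored at 0", call. = FALSE)
    qaly <- 0
  }

  # decedents accrue time-based costs only to the horizon midpoint
  alive_frac <- 1 - death / 2
  on_drug <- strategy != "untreated"
  cost_breakdown <- c(
    drug = v[[paste0("drug_cost_per_day.", strategy)]] * 365.25 * T * alive_frac,
    visits = if (on_drug) {
      v[["visit_frequency_per_month"]] * 12 * T * v[["visit_cost"]] * alive_frac
    } else 0,
    counts * event_cost)

  structure(list(strategy = strategy, age_group = age_group,
                 expected_cost_jpy = sum(cost_breakdown),
                 expected_qaly = qaly,
                 death_probability = death,
                 cost_breakdown = cost_breakdown,
                 qaly_breakdown = qaly_breakdown,
                 risks = risks),
            class = "strategy_result")
}

mix_results <- function(parts, weights, label) {
  stopifnot(length(parts) == length(weights), abs(sum(weights) - 1) < 1e-9)
  wsum <- function(f) Reduce(`+`, Map(function(p, w) w * f(p), parts, weights))
  structure(list(strategy = parts[[1]]$strategy, age_group = label,
                 expected_cost_jpy = wsum(function(p) p$expected_cost_jpy),
                 expected_qaly = wsum(function(p) p$expected_qaly),
                 death_probability = wsum(function(p) p$death_probability),
                 cost_breakdown = wsum(function(p) p$cost_breakdown),
                 qaly_breakdown = wsum(function(p) p$qaly_breakdown),
                 risks = NULL),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy_result> %s (%s): cost JPY %.0f, QALY %.4f, P(death) %.5f\n",
              x$strategy, x$age_group, x$expected_cost_jpy, x$expected_qaly,
              x$death_probability))
  invisible(x)
}

#' Expected QALYs / expected cost of a strategy
#'
#' Convenience scalar accessors over [evaluate_strategy()].
#'
#' @inheritParams evaluate_strategy
#' @return A single numeric value.
#' @export
expected_qaly <- function(strategy, age_group = "mixed", params) {
  evaluate_strategy(strategy, age_group, params)$expected_qaly
}

#' @rdname expected_qaly
#' @export
expected_cost <- function(strategy, age_group = "mixed", params) {
  evaluate_strategy(strategy, age_group, params)$expected_cost_jpy
}

#' Evaluate every strategy
#'
#' Runs the decision tree for all four strategies. The mixed population is
#' the component-wise convex combination of the per-stratum results under
#' the configured age weights, so evaluation is deterministic for a fixed
#' parameter set.
#'
#' @param params A validated [parameter_set()].
#' @param population `"mixed"` (default) or one of [age_groups()].
#' @return A named list of `strategy_result` objects, class
#'   `strategy_results`, one per strategy.
#' @export
evaluate_all <- function(params, population = "mixed") {
  stopifnot(inherits(params, "parameter_set"))
  out <- lapply(strategies(), evaluate_strategy, age_group = population,
                params = params)
  names(out) <- strategies()
  class(out) <- "strategy_results"
  out
}

#' @export
print.strategy_results <- function(x, ...) {
  for (r in x) print(r)
  invisible(x)
}

#' @export
as.data.frame.strategy_results <- function(x, ...) {
  data.frame(
    strategy = vapply(x, `[[`, "", "strategy"),
    age_group = vapply(x, `[[`, "", "age_group"),
    expected_cost_jpy = vapply(x, `[[`, 0, "expected_cost_jpy"),
    expected_qaly = vapply(x, `[[`, 0, "expected_qaly"),
    death_probability = vapply(x, `[[`, 0, "death_probability"),
    row.names = NULL
  )
}
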