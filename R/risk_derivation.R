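#' Chain multiplicative fall-risk effects
#'
#' Fall risks enter the model relative to the general (good-sleeper)
#' population: a drug's hazard ratio versus untreated insomnia is chained
#' with the relative risk of untreated insomnia versus the general population
#' (e.g. 0.68 x 1.48 for lemborexant, 0.85 x 1.48 for suvorexant). No
#' rounding is applied here; the reporting layer rounds.
#'
#' @param hr_drug_vs_untreated Hazard ratio of the drug versus untreated
#'   insomnia (> 0).
#' @param rr_untreated_vs_general Relative risk of untreated insomnia versus
#'   the general population (> 0).
#' @return The composed relative effect versus the general population.
#' @export
compose_fall_hazard <- function(hr_drug_vs_untreated, rr_untreated_vs_general) {
  if (!all(is.finite(c(hr_drug_vs_untreated, rr_untreated_vs_general))) ||
      hr_drug_vs_untreated <= 0 || rr_untreated_vs_general <= 0) {
    stop("relative effects must be finite and > 0", call. = FALSE)
  }
  hr_drug_vs_untreated * rr_untreated_vs_general
}

#' Response-weighted odds ratio for workplace accidents
#'
#' Treatment responders revert to the baseline workplace-accident risk
#' (odds ratio 1); non-responders keep the short-sleeper odds ratio. The
#' strategy-level effect is the response-weighted mixture
#' `r * 1 + (1 - r) * OR`, e.g. 0.207 x 1.0 + 0.793 x 1.79 = 1.63.
#'
#' @param response_rate Proportion of responders in \[0, 1\].
#' @param or_nonresponder Odds ratio for non-responders (> 0).
#' @return The weighted relative effect.
#' @export
weighted_event_or <- function(response_rate, or_nonresponder) {
  if (!is.finite(response_rate) || response_rate < 0 || response_rate > 1) {
    stop("response_rate must be in [0, 1]", call. = FALSE)
  }
  if (!is.finite(or_nonresponder) || or_nonresponder <= 0) {
    stop("or_nonresponder must be > 0", call. = FALSE)
  }
  response_rate * 1 + (1 - response_rate) * or_nonresponder
}

#' Expected number of falls per faller
#'
#' Groups with a higher proportion of fallers experience more falls per
#' faller. The relationship is linear, anchored at the survey estimate of
#' 1.957 falls per faller (so 0.957 extra falls beyond the first) at the
#' survey's annual faller proportion, with a regression slope; the result is
#' floored at 1 because a faller falls at least once. Expected per-capita
#' falls downstream are `p_faller * falls_per_faller(p_faller, ...)`.
#'
#' @param p_faller Proportion of fallers the group experiences.
#' @param anchor_rate Faller proportion at which the anchor was estimated.
#' @param anchor_falls Falls per faller at the anchor (>= 1).
#' @param slope Change in falls per faller per unit change in the faller
#'   proportion.
#' @return Falls per faller, >= 1.
#' @export
falls_per_faller <- function(p_faller, anchor_rate, anchor_falls, slope) {
  stopifnot(is.finite(p_faller), is.finite(anchor_rate),
            is.finite(anchor_falls), is.finite(slope), anchor_falls >= 1)
  max(1, anchor_falls + slope * (p_faller - anchor_rate))
}

#' Convert between annual and period event probabilities
#'
#' Constant-hazard conversion `1 - (1 - p_annual)^horizon_years`, the
#' standard rate-to-probability transform for decision models with a horizon
#' different from the period over which risks are reported. Strictly
#' increasing in both arguments; `period_to_annual_prob()` is its exact
#' inverse.
#'
#' @param p_annual Annual probability in \[0, 1\].
#' @param horizon_years Model horizon in years (> 0).
#' @return Probability over the horizon.
#' @export
annual_to_period_prob <- function(p_annual, horizon_years) {
  stopifnot(is.finite(horizon_years), horizon_years > 0)
  if (any(!is.finite(p_annual) | p_annual < 0 | p_annual > 1)) {
    stop("p_annual must be in [0, 1]", call. = FALSE)
  }
  if (any(p_annual == 1)) {
    warning("p_annual = 1 is a degenerate (infinite) hazard; returning 1",
            call. = FALSE)
  }
  1 - (1 - p_annual)^horizon_years
}

#' @rdname annual_to_period_prob
#' @param p_period Probability over the horizon.
#' @export
period_to_annual_prob <- function(p_period, horizon_years) {
  stopifnot(is.finite(horizon_years), horizon_years > 0)
  if (any(!is.finite(p_period) | p_period < 0 | p_period > 1)) {
    stop("p_period must be in [0, 1]", call. = FALSE)
  }
  1 - (1 - p_period)^(1 / horizon_years)
}

#' Partition fall outcomes into care levels
#'
#' Conditional on a fall: `1 - p_any_care` of fallers receive no medical
#' care, `p_any_care - p_admit` are treated as outpatients only, and the
#' admitted `p_admit` split into non-fracture admissions, non-hip fractures
#' and hip fractures (e.g. 8% admitted, 32% of admissions non-fracture, 53%
#' of fracture admissions hip -> 2.56%, 2.56%, 2.88% of all fallers).
#'
#' @param p_any_care Probability a faller receives any medical care.
#' @param p_admit Probability a faller is hospitalized (subset of any care).
#' @param admit_nonfracture_frac Fraction of admissions without fracture.
#' @param fracture_hip_frac Fraction of fracture admissions that are hip
#'   fractures.
#' @return An object of class `fall_outcome_split`: named numeric vector with
#'   `p_no_care`, `p_outpatient`, `p_admit_nonfracture`,
#'   `p_admit_nonhip_fracture`, `p_admit_hip_fracture` (sums to 1).
#' @export
fall_outcome_split <- function(p_any_care, p_admit, admit_nonfracture_frac,
                               fracture_hip_frac) {
  args <- c(p_any_care, p_admit, admit_nonfracture_frac, fracture_hip_frac)
  if (any(!is.finite(args) | args < 0 | args > 1)) {
    stop("all fall-pathway fractions must be in [0, 1]", call. = FALSE)
  }
  if (p_admit > p_any_care) {
    stop("p_admit (", p_admit, ") exceeds p_any_care (", p_any_care,
         "): admitted fallers are a subset of those receiving care",
         call. = FALSE)
  }
  p_fracture <- p_admit * (1 - admit_nonfracture_frac)
  structure(
    c(p_no_care = 1 - p_any_care,
      p_outpatient = p_any_care - p_admit,
      p_admit_nonfracture = p_admit * admit_nonfracture_frac,
      p_admit_nonhip_fracture = p_fracture * (1 - fracture_hip_frac),
      p_admit_hip_fracture = p_fracture * fracture_hip_frac),
    class = "fall_outcome_split")
}

#' Scale an annual event rate by an employment ratio
#'
#' Workplace-accident exposure in the older stratum is scaled by the older
#' population's employment ratio (24.3% of the younger rate in the base
#' case).
#'
#' @param annual_rate Annual event probability in \[0, 1\].
#' @param employment_ratio Employment ratio in \[0, 1\].
#' @return The scaled probability.
#' @export
scale_rate_by_employment <- function(annual_rate, employment_ratio) {
  args <- c(annual_rate, employment_ratio)
  if (any(!is.finite(args) | args < 0 | args > 1)) {
    stop("annual_rate and employment_ratio must be in [0, 1]", call. = FALSE)
  }
  annual_rate * employment_ratio
}

# Relative effect of a strategy on an event, versus the general population.
# Falls: drug HR vs untreated chained with the untreated-vs-general RR.
# MVC: the zolpidem-derived effect is applied to all three drugs; untreated
# keeps its own odds ratio. WPA: drugs use the response-weighted odds ratio;
# untreated the unweighted one (response rate 0 makes the two coincide).
relative_effect <- function(strategy, event, v) {
  strategy <- match.arg(strategy, strategies())
  event <- match.arg(event, events())
  switch(event,
    fall = if (strategy == "untreated") {
      v[["rr.fall.untreated_vs_general"]]
    } else {
      compose_fall_hazard(v[[paste0("hr.fall.", strategy, "_vs_untreated")]],
                          v[["rr.fall.untreated_vs_general"]])
    },
    mvc = if (strategy == "untreated") v[["or.mvc.untreated"]] else v[["or.mvc.hypnotic"]],
    wpa = weighted_event_or(v[[paste0("response_rate.", strategy)]],
                            v[["or.wpa.nonresponder"]]))
}

# Baseline annual risk of an event for an age stratum. The older stratum's
# workplace-accident rate is derived from the younger rate by employment
# scaling rather than stored.
baseline_annual_risk <- function(event, age_group, v) {
  if (event == "wpa") {
    r <- v[["baseline_annual_risk.wpa.younger"]]
    if (age_group == "older") {
      r <- scale_rate_by_employment(r, v[["employment_ratio_older"]])
    }
    r
  } else {
    v[[paste0("baseline_annual_risk.", event, ".", age_group)]]
  }
}

fall_split_from_values <- function(v) {
  fall_outcome_split(v[["fall_care.any_care"]], v[["fall_care.admission"]],
                     v[["fall_care.admit_nonfracture_frac"]],
                     v[["fall_care.fracture_hip_frac"]])
}

# Probability of death conditional on one fall: only admissions carry
# fatality risk; outpatient and no-care falls are minor injuries.
fall_death_per_fall <- function(split, v) {
  split[["p_admit_nonfracture"]] * v[["fatality.fall_admit_nonfracture"]] +
    split[["p_admit_nonhip_fracture"]] * v[["fatality.fall_admit_nonhip_fracture"]] +
    split[["p_admit_hip_fracture"]] * v[["fatality.fall_admit_hip_fracture"]]
}

#' Event risk profile of a strategy
#'
#' Composes, for one strategy, event and age stratum: the period probability
#' of the event (baseline annual risk x relative effect, converted to the
#' model horizon under a constant hazard), the expected events per capita
#' (falls are inflated by the falls-per-faller regression; collisions and
#' workplace accidents are counted once), and the probability of death
#' (falls: per-admission-type fatalities weighted by the care/fracture
#' split, applied to the first fall; collisions and workplace accidents: a
#' flat per-event fatality). A composite annual risk exceeding 1 is clipped
#' with a warning rather than failing, since one-way analysis can push
#' composed risks past 1.
#'
#' @param strategy One of [strategies()].
#' @param event One of [events()].
#' @param age_group One of [age_groups()].
#' @param params A validated [parameter_set()].
#' @return A list of class `event_risk_profile` with `event`, `strategy`,
#'   `age_group`, `period_probability`, `expected_count_per_capita`,
#'   `death_probability`.
#' @export
event_risk <- function(strategy, event, age_group, params) {
  stopifnot(inherits(params, "parameter_set"))
  v <- params$values
  age_group <- match.arg(age_group, age_groups())
  annual <- baseline_annual_risk(event, age_group, v) *
    relative_effect(strategy, event, v)
  if (annual > 1) {
    warning("composite annual risk ", signif(annual, 4), " for ", strategy,
            "/", event, "/", age_group, " clipped to 1", call. = FALSE)
    annual <- 1
  }
  p <- annual_to_period_prob(annual, v[["horizon_years"]])
  if (event == "fall") {
    count <- p * falls_per_faller(p, v[["refall.anchor_rate"]],
                                  v[["refall.anchor_falls"]],
                                  v[["refall.slope"]])
    death <- p * fall_death_per_fall(fall_split_from_values(v), v)
  } else {
    count <- p
    death <- p * v[[paste0("fatality.", event)]]
  }
  structure(list(event = event, strategy = strategy, age_group = age_group,
                 period_probability = p,
                 expected_count_per_capita = count,
                 death_probability = death),
            class = "event_risk_profile")
}
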