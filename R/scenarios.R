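#' Define a scenario
#'
#' A scenario restricts the population to one age stratum and/or swaps the
#' treatment-response definition. Alternative response measures (wake after
#' sleep onset, WASO; latency to persistent sleep, LPS) replace only the
#' per-strategy response rates and the matched chronic-insomnia utility
#' decrement; every other parameter is inherited from the base case, so the
#' overrides map may only touch `response_rate.*` and `insomnia_disutility`.
#'
#' @param name Scenario label.
#' @param age_restriction `NULL` (mixed population) or one of [age_groups()].
#' @param response_measure `"ssol"` (base case), `"waso"` or `"lps"`.
#' @param overrides Named list mapping permitted parameter ids to values;
#'   when empty and `response_measure != "ssol"`, the overrides are built
#'   from the parameter set's `scenario_response_rate.*` and
#'   `scenario_insomnia_disutility.*` entries at run time.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, age_restriction = NULL,
                          response_measure = c("ssol", "waso", "lps"),
                          overrides = list()) {
  response_measure <- match.arg(response_measure)
  if (!is.null(age_restriction)) {
    age_restriction <- match.arg(age_restriction, age_groups())
  }
  if (length(overrides)) {
    bad <- names(overrides)[!grepl("^response_rate\\.", names(overrides)) &
                              names(overrides) != "insomnia_disutility"]
    if (length(bad)) {
      stop("scenario overrides may only touch response rates and the ",
           "insomnia disutility; not permitted: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(name = name, age_restriction = age_restriction,
                 response_measure = response_measure, overrides = overrides),
            class = "scenario_spec")
}

measure_overrides <- function(params, measure) {
  ov <- as.list(params$values[paste0("scenario_response_rate.", measure, ".",
                                     strategies())])
  names(ov) <- paste0("response_rate.", strategies())
  ov$insomnia_disutility <-
    params$values[[paste0("scenario_insomnia_disutility.", measure)]]
  ov
}

#' Run a scenario analysis
#'
#' Applies the scenario's overrides to the base-case parameter set,
#' evaluates all four strategies for the scenario population, and compares
#' the intervention against each comparator. Response-measure scenarios only
#' move QALYs and (through the response-weighted workplace-accident effect)
#' a small workplace-accident cost component; drug and visit costs are
#' untouched.
#'
#' @param params Base-case [parameter_set()].
#' @param spec A [scenario_spec()].
#' @param intervention Strategy compared against the rest.
#' @return A list of class `scenario_result`: `spec`, `params` (the
#'   overridden set), `results` ([evaluate_all()] output) and `comparisons`
#'   ([compare_all()] output).
#' @export
run_scenario <- function(params, spec, intervention = "lemborexant") {
  stopifnot(inherits(params, "parameter_set"), inherits(spec, "scenario_spec"))
  overrides <- spec$overrides
  if (!length(overrides) && spec$response_measure != "ssol") {
    overrides <- measure_overrides(params, spec$response_measure)
  }
  ps <- params
  for (id in names(overrides)) {
    ps <- set_param_value(ps, id, overrides[[id]], validate = FALSE)
  }
  validate_parameter_set(ps)
  population <- if (is.null(spec$age_restriction)) "mixed" else spec$age_restriction
  results <- evaluate_all(ps, population)
  structure(list(spec = spec, params = ps, results = results,
                 comparisons = compare_all(results, intervention)),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> '%s' (population: %s, response measure: %s)\n",
              x$spec$name,
              if (is.null(x$spec$age_restriction)) "mixed" else x$spec$age_restriction,
              x$spec$response_measure))
  print(x$results)
  for (cmp in x$comparisons) print(cmp)
  invisible(x)
}

#' The standard scenario battery
#'
#' The four scenarios examined alongside the base case: each pure age
#' stratum under the base-case response definition, and the mixed population
#' under the WASO and LPS response definitions.
#'
#' @return A named list of [scenario_spec()] objects.
#' @export
standard_scenarios <- function() {
  list(
    younger = scenario_spec("younger adults (18-64)", age_restriction = "younger"),
    older = scenario_spec("older adults (65+)", age_restriction = "older"),
    waso = scenario_spec("WASO response definition", response_measure = "waso"),
    lps = scenario_spec("LPS response definition", response_measure = "lps")
  )
}
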