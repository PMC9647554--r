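#' @title Parameter sets
#' @description Internal list of every id a valid parameter set must carry.
#' @keywords internal
required_parameter_ids <- function() {
  c(
    paste0("response_rate.", strategies()),
    "insomnia_disutility", "utility_norm",
    paste0("baseline_annual_risk.fall.", age_groups()),
    paste0("baseline_annual_risk.mvc.", age_groups()),
    "baseline_annual_risk.wpa.younger",
    "employment_ratio_older",
    "rr.fall.untreated_vs_general",
    "hr.fall.lemborexant_vs_untreated",
    "hr.fall.suvorexant_vs_untreated",
    "hr.fall.zolpidem_ir_vs_untreated",
    "or.mvc.untreated", "or.mvc.hypnotic",
    "or.wpa.nonresponder",
    "fall_care.any_care", "fall_care.admission",
    "fall_care.admit_nonfracture_frac", "fall_care.fracture_hip_frac",
    "fatality.fall_admit_nonfracture", "fatality.fall_admit_nonhip_fracture",
    "fatality.fall_admit_hip_fracture",
    "fatality.mvc", "fatality.wpa",
    "cost.fall_outpatient", "cost.fall_admit_nonfracture",
    "cost.fall_admit_nonhip_fracture", "cost.fall_admit_hip_fracture",
    "cost.mvc", "cost.wpa",
    paste0("drug_cost_per_day.", strategies()),
    "visit_frequency_per_month", "visit_cost",
    "disutility.fall", "disutility.fracture_nonhip", "disutility.fracture_hip",
    "disutility.mvc", "disutility.wpa",
    "refall.anchor_falls", "refall.anchor_rate", "refall.slope",
    "refall.mean_falls_per_faller",
    paste0("age_weight.", age_groups()),
    "horizon_years", "wtp_jpy_per_qaly", "jpy_per_usd",
    "psa_draws", "psa_default_se_fraction", "owa_default_range_fraction",
    paste0("scenario_response_rate.waso.", strategies()),
    paste0("scenario_response_rate.lps.", strategies()),
    "scenario_insomnia_disutility.waso", "scenario_insomnia_disutility.lps"
  )
}

#' Assemble a validated parameter set
#'
#' A `parameter_set` is the complete collection of model inputs for one
#' evaluation: response rates per strategy, utilities, baseline annual
#' adverse-event risks per age stratum, relative treatment effects per event,
#' the fall care/fracture cascade, fatality probabilities, unit costs, the
#' re-fall regression anchor and slope, and analysis settings (horizon,
#' willingness-to-pay, exchange rate, sensitivity-analysis defaults).
#'
#' @param specs A list of [parameter_spec()] objects covering every required
#'   id (see `insomniaCEA:::required_parameter_ids()`).
#' @return An object of class `parameter_set` holding the input list and a
#'   named numeric vector of values for fast evaluation.
#' @seealso [reference_parameters()], [load_parameter_set()]
#' @export
parameter_set <- function(specs) {
  stopifnot(is.list(specs), all(vapply(specs, inherits, TRUE, "parameter_spec")))
  ids <- vapply(specs, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate parameter ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(specs) <- ids
  ps <- structure(
    list(specs = specs,
         values = stats::setNames(vapply(specs, `[[`, 0, "value"), ids)),
    class = "parameter_set")
  validate_parameter_set(ps)
  ps
}

#' Validate a parameter set
#'
#' Checks completeness and the cross-parameter invariants: the untreated
#' strategy has response rate 0, zero drug cost and no physician visits; age
#' weights sum to 1; the admitted fraction of fallers cannot exceed the
#' fraction receiving any care; the re-fall anchor is at least one fall per
#' faller; horizon, willingness-to-pay and exchange rate are positive.
#'
#' @param ps A [parameter_set()].
#' @return `ps`, invisibly; otherwise an error naming the offending ids.
#' @export
validate_parameter_set <- function(ps) {
  stopifnot(inherits(ps, "parameter_set"))
  missing <- setdiff(required_parameter_ids(), names(ps$specs))
  if (length(missing)) {
    stop("missing required parameters: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (spec in ps$specs) validate_parameter_spec(spec)
  v <- ps$values
  fail <- function(...) stop(..., call. = FALSE)
  if (v[["response_rate.untreated"]] != 0) {
    fail("response_rate.untreated must be 0 (untreated insomnia does not improve)")
  }
  if (v[["drug_cost_per_day.untreated"]] != 0) {
    fail("drug_cost_per_day.untreated must be 0")
  }
  w <- v[["age_weight.younger"]] + v[["age_weight.older"]]
  if (abs(w - 1) > 1e-9) {
    fail("age_weight.younger + age_weight.older must sum to 1 (got ", w, ")")
  }
  if (v[["fall_care.admission"]] > v[["fall_care.any_care"]]) {
    fail("fall_care.admission exceeds fall_care.any_care: ",
         "admitted fallers are a subset of fallers receiving care")
  }
  if (v[["refall.anchor_falls"]] < 1) {
    fail("refall.anchor_falls must be >= 1 (a faller falls at least once)")
  }
  for (id in c("horizon_years", "wtp_jpy_per_qaly", "jpy_per_usd")) {
    if (v[[id]] <= 0) fail(id, " must be > 0")
  }
  if (v[["psa_draws"]] < 1) fail("psa_draws must be >= 1")
  invisible(ps)
}

#' @export
print.parameter_set <- function(x, ...) {
  prov <- table(vapply(x$specs, `[[`, "", "provenance"))
  cat(sprintf("<parameter_set> %d parameters (%s)\n", length(x$specs),
              paste(sprintf("%s: %d", names(prov), prov), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.parameter_set <- function(x, ...) {
  data.frame(
    id = names(x$specs),
    value = unname(x$values),
    role = vapply(x$specs, `[[`, "", "role"),
    family = vapply(x$specs, `[[`, "", "family"),
    ci_low = vapply(x$specs, `[[`, 0, "ci_low"),
    ci_high = vapply(x$specs, `[[`, 0, "ci_high"),
    se = vapply(x$specs, `[[`, 0, "se"),
    provenance = vapply(x$specs, `[[`, "", "provenance"),
    source = vapply(x$specs, `[[`, "", "source"),
    row.names = NULL
  )
}

#' Read or replace a parameter value
#'
#' @param ps A [parameter_set()].
#' @param id Parameter id.
#' @param value Replacement value.
#' @param validate Re-run [validate_parameter_set()] after the replacement?
#'   Set `FALSE` only in tight loops that validate once at the end.
#' @return `param_value`: the numeric value. `set_param_value`: a modified
#'   copy of `ps`.
#' @export
param_value <- function(ps, id) {
  stopifnot(inherits(ps, "parameter_set"))
  if (!id %in% names(ps$values)) {
    stop("unknown parameter id: ", id, call. = FALSE)
  }
  ps$values[[id]]
}

#' @rdname param_value
#' @export
set_param_value <- function(ps, id, value, validate = TRUE) {
  stopifnot(inherits(ps, "parameter_set"))
  if (!id %in% names(ps$values)) {
    stop("unknown parameter id: ", id, call. = FALSE)
  }
  spec <- ps$specs[[id]]
  spec$value <- as.numeric(value)
  # keep the CI consistent with the invariant ci_low <= value <= ci_high
  if (!is.na(spec$ci_low) &&
      (value < spec$ci_low || value > spec$ci_high)) {
    spec$ci_low <- NA_real_
    spec$ci_high <- NA_real_
  }
  validate_parameter_spec(spec)
  ps$specs[[id]] <- spec
  ps$values[[id]] <- spec$value
  if (validate) validate_parameter_set(ps)
  ps
}

spec_to_list <- function(spec) {
  out <- list(value = spec$value, role = spec$role, family = spec$family,
              provenance = spec$provenance)
  if (!is.na(spec$ci_low)) out$ci_low <- spec$ci_low
  if (!is.na(spec$ci_high)) out$ci_high <- spec$ci_high
  if (!is.na(spec$se)) out$se <- spec$se
  if (nzchar(spec$source)) out$source <- spec$source
  if (!spec$vary_in_owa) out$vary_in_owa <- FALSE
  if (!spec$sample_in_psa) out$sample_in_psa <- FALSE
  out
}

#' Load a parameter set from a YAML configuration
#'
#' The configuration is a YAML mapping with a top-level `parameters:` key;
#' each entry maps a parameter id to `value`, `role`, and optionally
#' `family`, `ci_low`/`ci_high`, `se`, `provenance`, `source`,
#' `vary_in_owa`, `sample_in_psa`. All monetary values are JPY; all rates are
#' annual unless the id is suffixed `_per_month` or `_per_day`.
#'
#' @param path Path to a YAML file, or `text =` a YAML string.
#' @param text YAML text (alternative to `path`).
#' @return A validated [parameter_set()].
#' @export
load_parameter_set <- function(path = NULL, text = NULL) {
  cfg <- if (!is.null(text)) yaml::yaml.load(text) else yaml::read_yaml(path)
  if (is.null(cfg$parameters)) {
    stop("configuration has no 'parameters' mapping", call. = FALSE)
  }
  specs <- lapply(names(cfg$parameters), function(id) {
    p <- cfg$parameters[[id]]
    if (is.null(p$value) || is.null(p$role)) {
      stop("parameter '", id, "': 'value' and 'role' are required",
           call. = FALSE)
    }
    parameter_spec(
      id = id, value = p$value, role = p$role,
      family = if (is.null(p$family)) default_family_for_role(p$role) else p$family,
      ci_low = if (is.null(p$ci_low)) NA_real_ else p$ci_low,
      ci_high = if (is.null(p$ci_high)) NA_real_ else p$ci_high,
      se = if (is.null(p$se)) NA_real_ else p$se,
      provenance = if (is.null(p$provenance)) "placeholder" else p$provenance,
      source = if (is.null(p$source)) "" else p$source,
      vary_in_owa = if (is.null(p$vary_in_owa)) TRUE else p$vary_in_owa,
      sample_in_psa = if (is.null(p$sample_in_psa)) TRUE else p$sample_in_psa)
  })
  parameter_set(specs)
}

#' @rdname load_parameter_set
#' @param ps A [parameter_set()] to serialize.
#' @export
write_parameter_set <- function(ps, path) {
  stopifnot(inherits(ps, "parameter_set"))
  cfg <- list(parameters = lapply(ps$specs, spec_to_list))
  # 17 significant digits: doubles round-trip exactly through the text form
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}
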