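# Shared fixture helpers: all inputs are built in code at test time.

# Reference set with named value overrides applied (validated once at the end).
params_with <- function(..., base = reference_parameters()) {
  overrides <- list(...)
  ps <- base
  for (id in names(overrides)) {
    ps <- set_param_value(ps, id, overrides[[id]], validate = FALSE)
  }
  validate_parameter_set(ps)
  ps
}

# A configuration with no adverse events at all: every baseline risk zero.
# Further overrides are applied afterwards, so they win over the zeroing.
no_event_params <- function(...) {
  base <- params_with(
    baseline_annual_risk.fall.younger = 0,
    baseline_annual_risk.fall.older = 0,
    baseline_annual_risk.mvc.younger = 0,
    baseline_annual_risk.mvc.older = 0,
    baseline_annual_risk.wpa.younger = 0)
  params_with(..., base = base)
}

# Same parameter set with every distribution degenerate (point masses), so a
# PSA must reproduce the base case in every draw.
all_fixed_params <- function(base = reference_parameters()) {
  specs <- lapply(base$specs, function(s) {
    s$family <- "fixed"
    s
  })
  parameter_set(specs)
}

# Brute-force dominance classifier over the 9 sign combinations of
# (delta cost, delta effect): the oracle for the comparison labels.
oracle_label <- function(dc, de) {
  if (dc < 0 && de > 0) return("dominant")
  if (dc < 0 && de == 0) return("dominant")
  if (dc == 0 && de > 0) return("dominant")
  if (dc > 0 && de < 0) return("dominated")
  if (dc > 0 && de == 0) return("dominated")
  if (dc == 0 && de < 0) return("dominated")
  if (dc == 0 && de == 0) return("equal")
  "icer"
}

# Wrap a strategy_result-shaped stub for comparison tests.
stub_result <- function(cost, qaly, strategy = "a", age_group = "mixed") {
  structure(list(strategy = strategy, age_group = age_group,
                 expected_cost_jpy = cost, expected_qaly = qaly,
                 death_probability = 0,
                 cost_breakdown = c(drug = cost), qaly_breakdown = c(baseline = qaly)),
            class = "strategy_result")
}
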