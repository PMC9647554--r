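#' Model strategies, age groups and event pathways
#'
#' The model compares exactly four strategies: the dual orexin receptor
#' antagonists lemborexant and suvorexant, zolpidem immediate release, and
#' untreated insomnia. Untreated insomnia accrues no drug cost and no
#' physician visits. Two age strata are modelled (18-64 years and 65+),
#' differing only in baseline adverse-event risks; treatment efficacy is
#' age-independent. Three adverse-event pathways are tracked: falls (with a
#' care/fracture cascade), motor vehicle collisions and workplace accidents.
#'
#' @return Character vector of the valid names.
#' @export
strategies <- function() {
  c("lemborexant", "suvorexant", "zolpidem_ir", "untreated")
}

#' @rdname strategies
#' @export
age_groups <- function() c("younger", "older")

#' @rdname strategies
#' @export
events <- function() c("fall", "mvc", "wpa")

param_roles <- c("probability", "relative_effect", "cost_jpy", "utility",
                 "count_rate", "fraction")
param_families <- c("beta", "gamma", "lognormal", "normal", "fixed")

# Conventional second-order distribution per semantic role when the input
# names none: beta on [0,1] quantities, gamma on costs, lognormal on ratio
# effects, normal otherwise.
default_family_for_role <- function(role) {
  switch(role,
         probability = ,
         fraction = ,
         utility = "beta",
         cost_jpy = "gamma",
         relative_effect = "lognormal",
         "normal")
}

#' Create a single model input with uncertainty metadata
#'
#' A `parameter_spec` couples a point value with the metadata the sensitivity
#' machinery needs: a semantic role (which fixes the admissible domain), an
#' optional 95% confidence interval and/or standard error, a distribution
#' family for probabilistic sensitivity analysis, and a provenance flag
#' separating values printed in the source literature from placeholder
#' calibration values.
#'
#' @param id Unique parameter identifier (dot-separated hierarchy).
#' @param value Point (base-case) value.
#' @param role One of `"probability"`, `"relative_effect"`, `"cost_jpy"`,
#'   `"utility"`, `"count_rate"`, `"fraction"`.
#' @param family Distribution family for PSA: `"beta"`, `"gamma"`,
#'   `"lognormal"`, `"normal"` or `"fixed"`. Defaults by role (beta for
#'   probabilities/fractions/utilities, gamma for costs, lognormal for
#'   relative effects, normal otherwise).
#' @param ci_low,ci_high Optional 95% confidence bounds (both or neither).
#' @param se Optional standard error (non-negative). When absent but a CI is
#'   present, the normal approximation `(ci_high - ci_low)/3.92` is used.
#' @param provenance `"printed"` (value appears in the source literature) or
#'   `"placeholder"` (calibration value standing in for an unpublished cell).
#' @param source Free-text citation/location string.
#' @param vary_in_owa Include in one-way sensitivity analysis? Structural
#'   settings (horizon, willingness-to-pay, exchange rate, analysis settings)
#'   set this to `FALSE`.
#' @param sample_in_psa Sample in probabilistic sensitivity analysis?
#'
#' @return An object of class `parameter_spec`.
#' @export
parameter_spec <- function(id, value, role,
                           family = default_family_for_role(role),
                           ci_low = NA_real_, ci_high = NA_real_,
                           se = NA_real_,
                           provenance = c("printed", "placeholder"),
                           source = "",
                           vary_in_owa = TRUE,
                           sample_in_psa = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  role <- match.arg(role, param_roles)
  family <- match.arg(family, param_families)
  provenance <- match.arg(provenance)
  value <- as.numeric(value)
  if (!is.finite(value)) {
    stop("parameter '", id, "': value must be finite", call. = FALSE)
  }
  spec <- structure(
    list(id = id, value = value, role = role, family = family,
         ci_low = as.numeric(ci_low), ci_high = as.numeric(ci_high),
         se = as.numeric(se), provenance = provenance, source = source,
         vary_in_owa = isTRUE(vary_in_owa),
         sample_in_psa = isTRUE(sample_in_psa)),
    class = "parameter_spec")
  validate_parameter_spec(spec)
  spec
}

role_domain <- function(role) {
  switch(role,
         probability = ,
         fraction = ,
         utility = c(0, 1),
         cost_jpy = c(0, Inf),
         relative_effect = c(1e-12, Inf),
         c(-Inf, Inf))
}

validate_parameter_spec <- function(spec) {
  dom <- role_domain(spec$role)
  if (spec$role == "relative_effect" && spec$value <= 0) {
    stop("parameter '", spec$id, "': relative_effect must be > 0",
         call. = FALSE)
  }
  if (spec$value < dom[1] || spec$value > dom[2]) {
    stop("parameter '", spec$id, "': value ", spec$value,
         " outside the admissible domain [", dom[1], ", ", dom[2],
         "] for role '", spec$role, "'", call. = FALSE)
  }
  has_ci <- !is.na(spec$ci_low) && !is.na(spec$ci_high)
  if (xor(is.na(spec$ci_low), is.na(spec$ci_high))) {
    stop("parameter '", spec$id, "': ci_low and ci_high must be given together",
         call. = FALSE)
  }
  if (has_ci && !(spec$ci_low <= spec$value && spec$value <= spec$ci_high)) {
    stop("parameter '", spec$id, "': value must lie within [ci_low, ci_high]",
         call. = FALSE)
  }
  if (!is.na(spec$se) && spec$se < 0) {
    stop("parameter '", spec$id, "': se must be >= 0", call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.parameter_spec <- function(x, ...) {
  ci <- if (!is.na(x$ci_low)) sprintf(" CI [%g, %g]", x$ci_low, x$ci_high) else ""
  se <- if (!is.na(x$se)) sprintf(" se %g", x$se) else ""
  cat(sprintf("<parameter_spec> %s = %g (%s, %s%s%s, %s)\n",
              x$id, x$value, x$role, x$family, ci, se, x$provenance))
  invisible(x)
}

#' One-way sensitivity range of a parameter
#'
#' Returns the interval over which a parameter is varied in one-way
#' sensitivity analysis: its reported 95% confidence interval when available,
#' otherwise a symmetric relative band `value * (1 -/+ default_fraction)`.
#' Either way the result is clipped to the admissible domain of the
#' parameter's role (probabilities/fractions/utilities to [0,1], costs to
#' non-negative values, relative effects to positive values).
#'
#' @param spec A [parameter_spec()].
#' @param default_fraction Relative half-width used when no CI is available
#'   (default 0.20).
#' @return Numeric vector `c(low, high)`.
#' @export
owa_range <- function(spec, default_fraction = 0.20) {
  stopifnot(inherits(spec, "parameter_spec"),
            is.finite(spec$value), default_fraction >= 0)
  if (!is.na(spec$ci_low) && !is.na(spec$ci_high)) {
    lo <- spec$ci_low
    hi <- spec$ci_high
  } else {
    lo <- spec$value * (1 - default_fraction)
    hi <- spec$value * (1 + default_fraction)
  }
  dom <- role_domain(spec$role)
  c(low = max(dom[1], min(lo, hi)), high = min(dom[2], max(lo, hi)))
}

#' Second-order distribution of a parameter for probabilistic SA
#'
#' Moment-matches the parameter's distribution family to its base-case value
#' (as the mean) and standard error. When no standard error is recorded the
#' conventional default `default_se_fraction * value` is used. A value on the
#' boundary of the family's support (e.g. a probability of exactly 0 or 1
#' under a beta), or a dispersion incompatible with the family, degrades to a
#' degenerate point mass with a warning.
#'
#' When only a 95% confidence interval is recorded, the standard error is
#' recovered by the normal approximation `(ci_high - ci_low)/3.92`.
#'
#' @param spec A [parameter_spec()].
#' @param default_se_fraction Standard error as a fraction of the mean when
#'   none is recorded (default 0.10).
#' @return A list of class `psa_distribution` with elements `family`, `mean`,
#'   `sd` and family-specific shape values.
#' @export
psa_distribution <- function(spec, default_se_fraction = 0.10) {
  stopifnot(inherits(spec, "parameter_spec"))
  m <- spec$value
  s <- if (!is.na(spec$se)) {
    spec$se
  } else if (!is.na(spec$ci_low) && !is.na(spec$ci_high)) {
    (spec$ci_high - spec$ci_low) / 3.92
  } else {
    default_se_fraction * abs(m)
  }
  fam <- spec$family
  fixed <- function(reason = NULL) {
    if (!is.null(reason)) {
      warning("parameter '", spec$id, "': ", reason,
              "; using a point mass at ", m, call. = FALSE)
    }
    structure(list(id = spec$id, family = "fixed", mean = m, sd = 0),
              class = "psa_distribution")
  }
  if (fam == "fixed") return(fixed())
  # support-boundary degradation comes before the zero-dispersion shortcut so
  # that a probability of exactly 0 or 1 is flagged, not silently frozen
  if (fam == "beta" && (m <= 0 || m >= 1)) {
    return(fixed("mean on the beta support boundary"))
  }
  if (fam %in% c("gamma", "lognormal") && m <= 0) {
    return(fixed(paste("mean on the", fam, "support boundary")))
  }
  if (s == 0) return(fixed())
  out <- switch(fam,
    beta = {
      nu <- m * (1 - m) / s^2 - 1
      if (nu <= 0) return(fixed("sd too large for a beta with this mean"))
      list(shape1 = m * nu, shape2 = (1 - m) * nu)
    },
    gamma = list(shape = m^2 / s^2, rate = m / s^2),
    lognormal = {
      sdlog2 <- log(1 + s^2 / m^2)
      list(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
    },
    normal = list(mean_n = m, sd_n = s))
  structure(c(list(id = spec$id, family = fam, mean = m, sd = s), out),
            class = "psa_distribution")
}

#' @export
print.psa_distribution <- function(x, ...) {
  cat(sprintf("<psa_distribution> %s: %s(mean %g, sd %g)\n",
              x$id, x$family, x$mean, x$sd))
  invisible(x)
}

#' Quantile transform of a PSA distribution
#'
#' Maps uniform(0,1) deviates through the distribution's quantile function,
#' the sampling primitive used by [run_psa()] (inverse-CDF sampling keeps
#' per-parameter random streams independent of one another).
#'
#' @param dist A `psa_distribution` from [psa_distribution()].
#' @param u Uniform(0,1) deviates.
#' @return Numeric vector of draws, same length as `u`.
#' @export
psa_quantile <- function(dist, u) {
  stopifnot(inherits(dist, "psa_distribution"))
  switch(dist$family,
         fixed = rep(dist$mean, length(u)),
         beta = stats::qbeta(u, dist$shape1, dist$shape2),
         gamma = stats::qgamma(u, shape = dist$shape, rate = dist$rate),
         lognormal = stats::qlnorm(u, dist$meanlog, dist$sdlog),
         normal = stats::qnorm(u, dist$mean_n, dist$sd_n))
}
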