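# Stable 31-bit string hash used to give every parameter its own random
# stream: adding or removing a parameter leaves other parameters' draws
# untouched for a fixed master seed.
hash_parameter_id <- function(id) {
  h <- 0
  for (code in utf8ToInt(id)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

parameter_stream_seed <- function(seed, id, offset = 0L) {
  as.integer((as.numeric(seed) + hash_parameter_id(id) + as.numeric(offset)) %%
               2147483647)
}

comparison_metric <- function(intervention_res, comparator_res,
                              metric = c("nmb", "icer", "delta_cost"), wtp) {
  metric <- match.arg(metric)
  dc <- intervention_res$expected_cost_jpy - comparator_res$expected_cost_jpy
  de <- intervention_res$expected_qaly - comparator_res$expected_qaly
  switch(metric,
         nmb = wtp * de - dc,
         icer = dc / de,
         delta_cost = dc)
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-evaluates the pairwise comparison at each parameter's one-way range
#' endpoints ([owa_range()]: the 95% CI when recorded, otherwise +/- the
#' configured default fraction, clipped to the role's domain), holding all
#' other parameters at base case. The comparison outcome is the net monetary
#' benefit (`"nmb"`, the stable choice when the base case is dominant) or the
#' incremental cost-effectiveness ratio (`"icer"`); `"auto"` picks the ICER
#' only when the base case is a genuine trade-off. Entries are sorted by
#' descending outcome span, ready for a tornado diagram.
#'
#' @param params A validated [parameter_set()].
#' @param intervention,comparator Strategy names.
#' @param outcome `"auto"`, `"nmb"` or `"icer"`.
#' @param population `"mixed"` or one of [age_groups()].
#' @param parameter_ids Parameters to vary; default: every parameter flagged
#'   `vary_in_owa` with a non-degenerate range.
#' @return A data.frame of class `tornado` with columns `parameter_id`,
#'   `low_input`, `high_input`, `outcome_low`, `outcome_high`, `span`,
#'   sorted by descending `span`; attributes `outcome_metric`,
#'   `base_outcome` and `skipped` (named character vector of parameters that
#'   could not be evaluated, with reasons).
#' @export
one_way_analysis <- function(params, intervention = "lemborexant",
                             comparator = "untreated",
                             outcome = c("auto", "nmb", "icer"),
                             population = "mixed",
                             parameter_ids = NULL) {
  stopifnot(inherits(params, "parameter_set"))
  outcome <- match.arg(outcome)
  wtp <- params$values[["wtp_jpy_per_qaly"]]
  frac <- params$values[["owa_default_range_fraction"]]

  eval_pair <- function(ps) {
    list(i = evaluate_strategy(intervention, population, ps),
         c = evaluate_strategy(comparator, population, ps))
  }
  base <- eval_pair(params)
  if (outcome == "auto") {
    base_cmp <- compare_strategies(base$i, base$c)
    outcome <- if (base_cmp$label == "icer") "icer" else "nmb"
  }
  base_outcome <- comparison_metric(base$i, base$c, outcome, wtp)

  if (is.null(parameter_ids)) {
    parameter_ids <- names(params$specs)[vapply(params$specs, `[[`, TRUE,
                                                "vary_in_owa")]
  }
  rows <- list()
  skipped <- character()
  for (id in parameter_ids) {
    rng <- owa_range(params$specs[[id]], frac)
    if (rng[1] == rng[2]) next  # degenerate range carries no information
    ends <- tryCatch({
      vapply(rng, function(x) {
        ps <- set_param_value(params, id, x)
        pair <- eval_pair(ps)
        comparison_metric(pair$i, pair$c, outcome, wtp)
      }, 0)
    }, error = function(e) conditionMessage(e))
    if (is.character(ends) || any(!is.finite(ends))) {
      skipped[id] <- if (is.character(ends)) ends else "non-finite outcome"
      next
    }
    rows[[id]] <- data.frame(parameter_id = id,
                             low_input = rng[[1]], high_input = rng[[2]],
                             outcome_low = ends[[1]], outcome_high = ends[[2]],
                             span = abs(ends[[2]] - ends[[1]]))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(parameter_id = character(), low_input = numeric(),
                      high_input = numeric(), outcome_low = numeric(),
                      outcome_high = numeric(), span = numeric())
  }
  out <- out[order(-out$span), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("tornado", "data.frame"),
            outcome_metric = outcome, base_outcome = base_outcome,
            intervention = intervention, comparator = comparator,
            skipped = skipped)
}

#' Deterministic threshold search on one parameter
#'
#' Finds the value of one parameter at which a comparison criterion crosses
#' its target -- e.g. the comparator's fall hazard ratio at which the
#' intervention stops being cost-saving (`delta_cost` = 0) or at which the
#' ICER reaches the willingness-to-pay threshold -- by bisection on the
#' supplied bracket to a relative tolerance of 1e-6. Returns "no crossing"
#' when the criterion has the same sign at both bracket ends.
#'
#' @param params A validated [parameter_set()].
#' @param parameter_id The parameter varied.
#' @param intervention,comparator Strategy names.
#' @param criterion `"delta_cost"` (target 0), `"icer"` (target = the
#'   configured willingness-to-pay) or `"nmb"` (target 0); the target can be
#'   overridden.
#' @param bracket Numeric `c(low, high)` search interval.
#' @param target Criterion target; defaults as above.
#' @param population `"mixed"` or one of [age_groups()].
#' @param tol Relative bisection tolerance (default 1e-6).
#' @return A list of class `threshold_result`: `value` (the crossing, or
#'   `NA`), `crossing` (logical), `criterion`, `target`, `f_low`, `f_high`.
#' @export
threshold_search <- function(params, parameter_id,
                             intervention = "lemborexant",
                             comparator = "untreated",
                             criterion = c("delta_cost", "icer", "nmb"),
                             bracket,
                             target = NULL,
                             population = "mixed",
                             tol = 1e-6) {
  stopifnot(inherits(params, "parameter_set"), length(bracket) == 2,
            bracket[1] < bracket[2])
  criterion <- match.arg(criterion)
  wtp <- params$values[["wtp_jpy_per_qaly"]]
  if (is.null(target)) target <- if (criterion == "icer") wtp else 0

  f <- function(x) {
    ps <- set_param_value(params, parameter_id, x)
    val <- comparison_metric(evaluate_strategy(intervention, population, ps),
                             evaluate_strategy(comparator, population, ps),
                             criterion, wtp) - target
    if (!is.finite(val)) {
      stop("criterion '", criterion, "' is non-finite at ", parameter_id,
           " = ", x, call. = FALSE)
    }
    val
  }
  lo <- bracket[1]; hi <- bracket[2]
  flo <- f(lo); fhi <- f(hi)
  result <- function(value, crossing) {
    structure(list(value = value, crossing = crossing, criterion = criterion,
                   target = target, parameter_id = parameter_id,
                   f_low = flo, f_high = fhi),
              class = "threshold_result")
  }
  if (flo == 0) return(result(lo, TRUE))
  if (fhi == 0) return(result(hi, TRUE))
  if (sign(flo) == sign(fhi)) return(result(NA_real_, FALSE))
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    if ((hi - lo) <= tol * max(1, abs(mid))) break
    fmid <- f(mid)
    if (fmid == 0) return(result(mid, TRUE))
    if (sign(fmid) == sign(flo)) {
      lo <- mid; flo <- fmid
    } else {
      hi <- mid; fhi <- fmid
    }
  }
  result((lo + hi) / 2, TRUE)
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$crossing) {
    cat(sprintf("<threshold_result> %s: %s crosses %g at %g\n",
                x$parameter_id, x$criterion, x$target, x$value))
  } else {
    cat(sprintf("<threshold_result> %s: no crossing of %s = %g in bracket\n",
                x$parameter_id, x$criterion, x$target))
  }
  invisible(x)
}

values_plausible <- function(values, specs) {
  for (id in names(specs)) {
    dom <- role_domain(specs[[id]]$role)
    x <- values[[id]]
    if (!is.finite(x) || x < dom[1] || x > dom[2]) return(FALSE)
  }
  values[["refall.anchor_falls"]] >= 1 &&
    values[["fall_care.admission"]] <= values[["fall_care.any_care"]] &&
    values[["visit_frequency_per_month"]] >= 0 &&
    values[["horizon_years"]] > 0
}

#' Probabilistic sensitivity analysis (Monte Carlo)
#'
#' Samples every parameter flagged for PSA independently from its
#' moment-matched second-order distribution ([psa_distribution()]), re-runs
#' the full decision tree per draw, and records the incremental cost and
#' incremental QALYs of the intervention against each comparator. Sampling
#' is inverse-CDF with one random stream per parameter (seeded from the
#' master seed and a hash of the parameter id), so results are reproducible
#' bitwise for a fixed `(params, n_draws, seed)` and adding a parameter does
#' not perturb the other parameters' draws. A draw that violates a
#' cross-parameter invariant (e.g. an admitted fraction exceeding the
#' any-care fraction) is resampled; the resample count is recorded.
#'
#' @param params A validated [parameter_set()].
#' @param seed Integer master seed.
#' @param n_draws Number of draws; default the configured `psa_draws`.
#' @param intervention Strategy compared against all others.
#' @param population `"mixed"` or one of [age_groups()].
#' @return A data.frame of class `psa_result` with columns `draw`,
#'   `comparator`, `delta_cost_jpy`, `delta_qaly`; attributes
#'   `parameter_draws` (draws x parameters matrix), `base_comparisons`,
#'   `resamples`, `seed`, `wtp`.
#' @export
run_psa <- function(params, seed, n_draws = NULL,
                    intervention = "lemborexant", population = "mixed") {
  stopifnot(inherits(params, "parameter_set"), is.numeric(seed))
  if (is.null(n_draws)) n_draws <- as.integer(params$values[["psa_draws"]])
  stopifnot(n_draws >= 1)
  se_frac <- params$values[["psa_default_se_fraction"]]

  sampled_ids <- names(params$specs)[vapply(params$specs, `[[`, TRUE,
                                            "sample_in_psa")]
  dists <- lapply(params$specs[sampled_ids], psa_distribution,
                  default_se_fraction = se_frac)
  sampled_ids <- sampled_ids[vapply(dists, `[[`, "", "family") != "fixed"]
  dists <- dists[sampled_ids]

  draws <- matrix(0, nrow = n_draws, ncol = length(sampled_ids),
                  dimnames = list(NULL, sampled_ids))
  for (id in sampled_ids) {
    set.seed(parameter_stream_seed(seed, id))
    draws[, id] <- psa_quantile(dists[[id]], stats::runif(n_draws))
  }

  comparators <- setdiff(strategies(), intervention)
  base_results <- evaluate_all(params, population)
  base_comparisons <- compare_all(base_results, intervention)

  n_resample <- 0L
  ps <- params
  rows_dc <- matrix(0, n_draws, length(comparators),
                    dimnames = list(NULL, comparators))
  rows_de <- rows_dc
  for (j in seq_len(n_draws)) {
    vals <- params$values
    vals[sampled_ids] <- draws[j, ]
    attempt <- 0L
    while (!values_plausible(vals, params$specs)) {
      attempt <- attempt + 1L
      n_resample <- n_resample + 1L
      if (attempt > 100L) {
        stop("draw ", j, " could not be resampled to a valid parameter set",
             call. = FALSE)
      }
      for (id in sampled_ids) {
        set.seed(parameter_stream_seed(seed, id, offset = j * 101L + attempt))
        vals[[id]] <- psa_quantile(dists[[id]], stats::runif(1))
      }
      draws[j, ] <- vals[sampled_ids]
    }
    ps$values <- vals
    res_i <- evaluate_strategy(intervention, population, ps)
    for (cmp in comparators) {
      res_c <- evaluate_strategy(cmp, population, ps)
      rows_dc[j, cmp] <- res_i$expected_cost_jpy - res_c$expected_cost_jpy
      rows_de[j, cmp] <- res_i$expected_qaly - res_c$expected_qaly
    }
  }

  out <- data.frame(
    draw = rep(seq_len(n_draws), times = length(comparators)),
    comparator = rep(comparators, each = n_draws),
    delta_cost_jpy = as.vector(rows_dc),
    delta_qaly = as.vector(rows_de))
  structure(out, class = c("psa_result", "data.frame"),
            parameter_draws = draws, base_comparisons = base_comparisons,
            intervention = intervention, resamples = n_resample, seed = seed,
            wtp = params$values[["wtp_jpy_per_qaly"]])
}

#' Summaries of a probabilistic sensitivity analysis
#'
#' Per comparison: the probability the intervention is cost-saving (jointly
#' `delta_cost < 0` and `delta_qaly >= 0`, with the marginal `delta_cost <
#' 0` fraction reported alongside), the probability it is cost-effective
#' (positive net monetary benefit) at the willingness-to-pay threshold, and
#' a cost-effectiveness acceptability curve over a threshold grid that
#' always includes 0 and the configured threshold.
#'
#' @param psa A [run_psa()] result.
#' @param wtp Willingness to pay; default the value stored with the PSA.
#' @param ceac_grid Thresholds for the acceptability curve; default an even
#'   grid from 0 to twice `wtp`.
#' @return A list of class `psa_summary`: `summary` (data.frame with one row
#'   per comparator) and `ceac` (data.frame `wtp` x `comparator` x
#'   `p_cost_effective`).
#' @export
psa_summary <- function(psa, wtp = NULL, ceac_grid = NULL) {
  stopifnot(inherits(psa, "psa_result"), nrow(psa) > 0)
  if (is.null(wtp)) wtp <- attr(psa, "wtp")
  if (is.null(ceac_grid)) ceac_grid <- seq(0, 2 * wtp, length.out = 41)
  ceac_grid <- sort(unique(c(0, wtp, ceac_grid)))

  comparators <- unique(psa$comparator)
  summ <- do.call(rbind, lapply(comparators, function(cmp) {
    s <- psa[psa$comparator == cmp, ]
    data.frame(
      comparator = cmp,
      n_draws = nrow(s),
      p_cost_saving = mean(s$delta_cost_jpy < 0 & s$delta_qaly >= 0),
      p_cost_saving_marginal = mean(s$delta_cost_jpy < 0),
      p_cost_effective = mean(wtp * s$delta_qaly - s$delta_cost_jpy > 0))
  }))
  ceac <- do.call(rbind, lapply(comparators, function(cmp) {
    s <- psa[psa$comparator == cmp, ]
    data.frame(
      wtp = ceac_grid,
      comparator = cmp,
      p_cost_effective = vapply(ceac_grid, function(k) {
        mean(k * s$delta_qaly - s$delta_cost_jpy > 0)
      }, 0))
  }))
  structure(list(summary = summ, ceac = ceac, wtp = wtp),
            class = "psa_summary")
}

#' @export
print.psa_summary <- function(x, ...) {
  cat(sprintf("<psa_summary> at WTP JPY %.0f/QALY:\n", x$wtp))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Cost-effectiveness plane scatter data
#'
#' The (incremental QALY, incremental cost) pairs per draw and comparison,
#' ready for a CE-plane plot.
#'
#' @param psa A [run_psa()] result.
#' @return A data.frame with `draw`, `comparator`, `delta_qaly`,
#'   `delta_cost_jpy`.
#' @export
ce_plane_data <- function(psa) {
  stopifnot(inherits(psa, "psa_result"))
  data.frame(draw = psa$draw, comparator = psa$comparator,
             delta_qaly = psa$delta_qaly, delta_cost_jpy = psa$delta_cost_jpy)
}
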