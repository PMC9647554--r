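test_that("tornado entries are sorted and bracket evaluations match direct reruns", {
  ps <- reference_parameters()
  tor <- one_way_analysis(ps, "lemborexant", "suvorexant")
  expect_s3_class(tor, "tornado")
  expect_true(all(diff(tor$span) <= 1e-12))
  expect_identical(attr(tor, "outcome_metric"), "nmb")  # dominant base case

  # a parameter with no model influence spans zero
  row <- tor[tor$parameter_id == "refall.mean_falls_per_faller", ]
  expect_equal(row$span, 0)

  # two-point oracle: re-evaluate the model directly at one entry's endpoints
  wtp <- param_value(ps, "wtp_jpy_per_qaly")
  id <- "hr.fall.suvorexant_vs_untreated"
  row <- tor[tor$parameter_id == id, ]
  for (end in c("low", "high")) {
    ps2 <- set_param_value(ps, id, row[[paste0(end, "_input")]])
    i <- evaluate_strategy("lemborexant", "mixed", ps2)
    c <- evaluate_strategy("suvorexant", "mixed", ps2)
    nmb <- wtp * (i$expected_qaly - c$expected_qaly) -
      (i$expected_cost_jpy - c$expected_cost_jpy)
    expect_equal(row[[paste0("outcome_", end)]], nmb, tolerance = 1e-9)
  }
  # raising the comparator's fall hazard monotonically favours the intervention
  expect_gt(row$outcome_high, attr(tor, "base_outcome"))
  expect_lt(row$outcome_low, attr(tor, "base_outcome"))
})

test_that("tornado endpoints bracket the base case for monotone parameters", {
  ps <- reference_parameters()
  tor <- one_way_analysis(ps, "lemborexant", "untreated")
  base <- attr(tor, "base_outcome")
  monotone <- c("hr.fall.lemborexant_vs_untreated", "rr.fall.untreated_vs_general",
                "insomnia_disutility", "drug_cost_per_day.lemborexant",
                "visit_cost")
  for (id in monotone) {
    row <- tor[tor$parameter_id == id, ]
    expect_true(min(row$outcome_low, row$outcome_high) <= base + 1e-9, info = id)
    expect_true(max(row$outcome_low, row$outcome_high) >= base - 1e-9, info = id)
  }
})

test_that("a perturbation that invalidates the parameter set is skipped with a reason", {
  # the re-fall anchor's printed CI dips below one fall per faller, which the
  # parameter-set invariants reject at the low endpoint
  tor <- one_way_analysis(reference_parameters(), "lemborexant", "zolpidem_ir")
  skipped <- attr(tor, "skipped")
  expect_true("refall.anchor_falls" %in% names(skipped))
  expect_match(skipped[["refall.anchor_falls"]], "anchor_falls")
  expect_false("refall.anchor_falls" %in% tor$parameter_id)
})

test_that("threshold search matches the closed-form root of a linear criterion", {
  # delta cost between the intervention and untreated is linear in the
  # collision unit cost, so the root follows from two evaluations
  ps <- reference_parameters()
  f <- function(x) {
    ps2 <- set_param_value(ps, "cost.mvc", x)
    expected_cost("lemborexant", "mixed", ps2) -
      expected_cost("untreated", "mixed", ps2)
  }
  x <- c(0, 4e7)
  root <- x[1] - f(x[1]) * (x[2] - x[1]) / (f(x[2]) - f(x[1]))
  hit <- threshold_search(ps, "cost.mvc", "lemborexant", "untreated",
                          criterion = "delta_cost", bracket = x)
  expect_true(hit$crossing)
  expect_equal(hit$value, root, tolerance = 1e-5)
  expect_lt(abs(f(hit$value)), abs(f(x[2]) - f(x[1])) * 1e-5)

  # a bracket without a sign change reports no crossing
  none <- threshold_search(ps, "cost.mvc", "lemborexant", "untreated",
                           criterion = "delta_cost", bracket = c(0, 1e5))
  expect_false(none$crossing)
  expect_true(is.na(none$value))
})

test_that("threshold search agrees with a dense grid scan", {
  # the comparator fall hazard at which the intervention stops being
  # cost-saving, scanned over 1000 grid points as the oracle
  ps <- reference_parameters()
  id <- "hr.fall.zolpidem_ir_vs_untreated"
  grid <- seq(0.25, 4, length.out = 1000)
  dc <- vapply(grid, function(x) {
    ps2 <- set_param_value(ps, id, x)
    suppressWarnings(expected_cost("lemborexant", "mixed", ps2) -
                       expected_cost("zolpidem_ir", "mixed", ps2))
  }, 0)
  flip <- which(diff(sign(dc)) != 0)
  expect_length(flip, 1)
  hit <- suppressWarnings(
    threshold_search(ps, id, "lemborexant", "zolpidem_ir",
                     criterion = "delta_cost", bracket = c(0.25, 4)))
  expect_true(hit$crossing)
  expect_gte(hit$value, grid[flip])
  expect_lte(hit$value, grid[flip + 1])
  # base case: the intervention is cost-saving above the crossing
  expect_gt(param_value(ps, id), hit$value)
})

test_that("PSA is reproducible bitwise under a fixed seed", {
  ps <- reference_parameters()
  a <- run_psa(ps, seed = 123, n_draws = 200)
  b <- run_psa(ps, seed = 123, n_draws = 200)
  expect_identical(attr(a, "parameter_draws"), attr(b, "parameter_draws"))
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- run_psa(ps, seed = 124, n_draws = 200)
  expect_false(identical(attr(a, "parameter_draws"), attr(c, "parameter_draws")))
})

test_that("per-parameter streams are unchanged when another parameter is added", {
  ps <- reference_parameters()
  a <- run_psa(ps, seed = 9, n_draws = 50)
  # freeze one sampled parameter: every other parameter's draws are untouched
  specs <- ps$specs
  specs[["or.mvc.hypnotic"]]$family <- "fixed"
  ps2 <- parameter_set(specs)
  b <- run_psa(ps2, seed = 9, n_draws = 50)
  shared <- setdiff(colnames(attr(a, "parameter_draws")), "or.mvc.hypnotic")
  expect_identical(attr(a, "parameter_draws")[, shared],
                   attr(b, "parameter_draws")[, shared])
})

test_that("an all-degenerate PSA reproduces the base case in every draw", {
  ps <- all_fixed_params()
  base <- compare_all(evaluate_all(ps))
  psa <- run_psa(ps, seed = 5, n_draws = 25)
  for (cmp in names(base)) {
    s <- psa[psa$comparator == cmp, ]
    expect_equal(s$delta_cost_jpy, rep(base[[cmp]]$delta_cost_jpy, 25),
                 tolerance = 0)
    expect_equal(s$delta_qaly, rep(base[[cmp]]$delta_qaly, 25), tolerance = 0)
  }
})

test_that("PSA sample means approach the base case as draws grow", {
  # symmetric-moment configuration: normal families with small dispersion so
  # the model is locally linear and the draw means converge on the base case
  specs <- lapply(reference_parameters()$specs, function(s) {
    if (s$family != "fixed") {
      s$family <- "normal"
      s$se <- 0.01 * abs(s$value)
      s$ci_low <- NA_real_
      s$ci_high <- NA_real_
    }
    s
  })
  ps <- parameter_set(specs)
  base <- compare_all(evaluate_all(ps))
  psa <- run_psa(ps, seed = 77, n_draws = 20000)
  for (cmp in names(base)) {
    s <- psa[psa$comparator == cmp, ]
    n <- nrow(s)
    expect_lt(abs(mean(s$delta_cost_jpy) - base[[cmp]]$delta_cost_jpy),
              3 * sd(s$delta_cost_jpy) / sqrt(n))
    expect_lt(abs(mean(s$delta_qaly) - base[[cmp]]$delta_qaly),
              3 * sd(s$delta_qaly) / sqrt(n))
  }
})

test_that("PSA summaries count cost-saving and cost-effective draws", {
  # hand-built four-draw sample: exactly one cost-saving draw
  samples <- structure(
    data.frame(draw = 1:4, comparator = "untreated",
               delta_cost_jpy = c(-100, 50, 200, 10),
               delta_qaly = c(0.001, 0.002, -0.001, 0)),
    class = c("psa_result", "data.frame"), wtp = 5e6)
  summ <- psa_summary(samples)
  expect_equal(summ$summary$p_cost_saving, 0.25)
  expect_equal(summ$summary$p_cost_saving_marginal, 0.25)
  # NMB > 0 at 5e6: 5100, 9950, -5200, -10 -> half the draws
  expect_equal(summ$summary$p_cost_effective, 0.5)
  # the acceptability curve at zero threshold is the cost-saving fraction
  at0 <- summ$ceac[summ$ceac$wtp == 0, ]
  expect_equal(at0$p_cost_effective, 0.25)
  expect_true(5e6 %in% summ$ceac$wtp)

  # all draws dominant: both fractions are one
  dom <- structure(
    data.frame(draw = 1:3, comparator = "suvorexant",
               delta_cost_jpy = c(-1, -2, -3), delta_qaly = c(0.1, 0.2, 0.3)),
    class = c("psa_result", "data.frame"), wtp = 5e6)
  sd2 <- psa_summary(dom)
  expect_equal(sd2$summary$p_cost_saving, 1)
  expect_equal(sd2$summary$p_cost_effective, 1)
})
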