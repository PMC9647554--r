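test_that("QALY accrual matches hand arithmetic in degenerate configurations", {
  u <- param_value(reference_parameters(), "utility_norm")

  # full response, no events: the population norm over the horizon, exactly
  ps <- no_event_params(response_rate.lemborexant = 1)
  expect_equal(expected_qaly("lemborexant", "mixed", ps), 0.5 * u,
               tolerance = 1e-15)

  # no response, no events: norm minus the insomnia decrement
  d <- param_value(ps, "insomnia_disutility")
  expect_equal(expected_qaly("untreated", "mixed", ps), 0.5 * (u - d),
               tolerance = 1e-15)

  # one event type with expected count 0.1, disutility 0.05, no deaths:
  # annual risk chosen so the period probability is exactly 0.1
  ps1 <- no_event_params(
    baseline_annual_risk.mvc.younger = 1 - 0.9^2,
    baseline_annual_risk.mvc.older = 1 - 0.9^2,
    or.mvc.untreated = 1, fatality.mvc = 0, disutility.mvc = 0.05,
    insomnia_disutility = 0)
  expect_equal(expected_qaly("untreated", "mixed", ps1), 0.5 * u - 0.1 * 0.05,
               tolerance = 1e-12)
})

test_that("cost accrual matches day-count and visit arithmetic", {
  ps <- no_event_params(visit_cost = 0)
  expect_equal(expected_cost("untreated", "mixed", ps), 0)
  expect_equal(expected_cost("lemborexant", "mixed", ps), 92 * 182.625,
               tolerance = 1e-9)

  # visit component: 1.3 visits/month over 6 months at the visit fee
  fee <- param_value(reference_parameters(), "visit_cost")
  ps2 <- no_event_params(drug_cost_per_day.lemborexant = 0)
  expect_equal(expected_cost("lemborexant", "mixed", ps2), 1.3 * 6 * fee,
               tolerance = 1e-9)
})

test_that("decedents accrue time-based costs to the horizon midpoint", {
  ps <- no_event_params(visit_cost = 0)
  # a single fatal event pathway: deaths scale the drug cost by 1 - p/2
  ps <- params_with(base = ps,
                    baseline_annual_risk.mvc.younger = 1 - 0.9^2,
                    baseline_annual_risk.mvc.older = 1 - 0.9^2,
                    or.mvc.hypnotic = 1, fatality.mvc = 0.5, cost.mvc = 0)
  res <- evaluate_strategy("lemborexant", "mixed", ps)
  expect_equal(res$death_probability, 0.05, tolerance = 1e-12)
  expect_equal(res$cost_breakdown[["drug"]], 92 * 182.625 * (1 - 0.025),
               tolerance = 1e-9)
  # and deaths forfeit half a horizon of norm utility
  expect_equal(res$qaly_breakdown[["death"]],
               -0.05 * param_value(ps, "utility_norm") * 0.25,
               tolerance = 1e-12)
})

test_that("strategy results satisfy their structural invariants", {
  for (seed in c(1, 2, 3)) {
    ps <- random_parameters(seed)
    u <- param_value(ps, "utility_norm")
    for (s in strategies()) {
      res <- suppressWarnings(evaluate_strategy(s, "mixed", ps))
      expect_equal(res$expected_cost_jpy, sum(res$cost_breakdown),
                   tolerance = 1e-6)
      expect_equal(res$expected_qaly, sum(res$qaly_breakdown),
                   tolerance = 1e-9)
      expect_gte(res$expected_qaly, 0)
      expect_lte(res$expected_qaly, u * 0.5 + 1e-12)
      expect_gte(res$expected_cost_jpy, 0)
    }
  }
})

test_that("degenerate age weights reduce the mixed result to one stratum", {
  ps <- params_with(age_weight.younger = 1, age_weight.older = 0)
  for (s in strategies()) {
    mixed <- evaluate_strategy(s, "mixed", ps)
    young <- evaluate_strategy(s, "younger", ps)
    expect_equal(mixed$expected_cost_jpy, young$expected_cost_jpy)
    expect_equal(mixed$expected_qaly, young$expected_qaly)
    expect_equal(mixed$death_probability, young$death_probability)
  }
})

test_that("the mixed population is a convex combination of the strata", {
  ps <- params_with(age_weight.younger = 0.37, age_weight.older = 0.63)
  for (s in c("lemborexant", "untreated")) {
    mixed <- evaluate_strategy(s, "mixed", ps)
    young <- evaluate_strategy(s, "younger", ps)
    old <- evaluate_strategy(s, "older", ps)
    expect_equal(mixed$expected_cost_jpy,
                 0.37 * young$expected_cost_jpy + 0.63 * old$expected_cost_jpy,
                 tolerance = 1e-9)
    expect_equal(mixed$qaly_breakdown,
                 0.37 * young$qaly_breakdown + 0.63 * old$qaly_breakdown,
                 tolerance = 1e-12)
    expect_equal(mixed$cost_breakdown,
                 0.37 * young$cost_breakdown + 0.63 * old$cost_breakdown,
                 tolerance = 1e-9)
  }
})

test_that("reference QALYs order as intervention >= suvorexant >= untreated >= zolpidem", {
  res <- evaluate_all(reference_parameters())
  q <- vapply(res, `[[`, 0, "expected_qaly")
  expect_gte(q[["lemborexant"]], q[["suvorexant"]])
  expect_gte(q[["suvorexant"]], q[["untreated"]])
  expect_gte(q[["untreated"]], q[["zolpidem_ir"]])
})

test_that("evaluation is deterministic for a fixed parameter set", {
  ps <- reference_parameters()
  a <- evaluate_all(ps)
  b <- evaluate_all(ps)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("raising an event risk weakly lowers QALYs and raises costs", {
  ps <- reference_parameters()
  bumped <- params_with(
    baseline_annual_risk.fall.older =
      1.2 * param_value(ps, "baseline_annual_risk.fall.older"))
  for (s in strategies()) {
    expect_lte(expected_qaly(s, "mixed", bumped), expected_qaly(s, "mixed", ps))
    expect_gte(expected_cost(s, "mixed", bumped), expected_cost(s, "mixed", ps))
  }
})

test_that("raising a response rate raises QALYs and leaves drug/visit costs alone", {
  # workplace-accident fatality zeroed so deaths cannot couple the response
  # rate to the midpoint accrual of time-based costs
  ps <- params_with(fatality.wpa = 0)
  bumped <- params_with(fatality.wpa = 0, response_rate.lemborexant = 0.35)
  expect_gt(expected_qaly("lemborexant", "mixed", bumped),
            expected_qaly("lemborexant", "mixed", ps))
  a <- evaluate_strategy("lemborexant", "mixed", bumped)
  b <- evaluate_strategy("lemborexant", "mixed", ps)
  expect_identical(a$cost_breakdown[["drug"]], b$cost_breakdown[["drug"]])
  expect_identical(a$cost_breakdown[["visits"]], b$cost_breakdown[["visits"]])
  expect_identical(a$cost_breakdown[["fall"]], b$cost_breakdown[["fall"]])
  expect_identical(a$cost_breakdown[["mvc"]], b$cost_breakdown[["mvc"]])
})
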