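test_that("fall hazard chaining reproduces the printed products", {
  expect_equal(compose_fall_hazard(0.85, 1.48), 1.258, tolerance = 1e-12)
  expect_equal(round(compose_fall_hazard(0.85, 1.48), 2), 1.26)
  expect_equal(compose_fall_hazard(0.68, 1.48), 1.0064, tolerance = 1e-12)
  expect_equal(compose_fall_hazard(1, 1), 1)
  expect_error(compose_fall_hazard(-0.5, 1.48), "> 0")
  expect_error(compose_fall_hazard(0.5, 0), "> 0")
})

test_that("fall hazard chaining is commutative and associative", {
  set.seed(5)
  for (i in 1:25) {
    x <- exp(runif(3, -1.5, 1.5))
    expect_equal(compose_fall_hazard(x[1], x[2]), compose_fall_hazard(x[2], x[1]))
    expect_equal(compose_fall_hazard(compose_fall_hazard(x[1], x[2]), x[3]),
                 compose_fall_hazard(x[1], compose_fall_hazard(x[2], x[3])),
                 tolerance = 1e-12)
  }
})

test_that("response-weighted odds ratio matches the printed 1.63 example", {
  expect_equal(weighted_event_or(0.207, 1.79), 0.207 * 1 + 0.793 * 1.79,
               tolerance = 1e-12)
  expect_equal(round(weighted_event_or(0.207, 1.79), 2), 1.63)
  expect_equal(weighted_event_or(1, 1.79), 1)
  expect_equal(weighted_event_or(0, 1.79), 1.79)
})

test_that("response weighting is a convex combination of 1 and the odds ratio", {
  set.seed(6)
  for (i in 1:50) {
    r <- runif(1)
    or <- exp(runif(1, -1.5, 1.5))
    w <- weighted_event_or(r, or)
    expect_gte(w, min(1, or) - 1e-15)
    expect_lte(w, max(1, or) + 1e-15)
  }
})

test_that("falls per faller anchors at 1.957 and respects the floor", {
  expect_equal(falls_per_faller(0.25, 0.25, 1.957, 2.7), 1.957)
  expect_equal(falls_per_faller(0.25, 0.25, 1.957, 2.7) - 1, 0.957)
  # slope 0: constant
  for (p in c(0, 0.2, 0.9)) {
    expect_equal(falls_per_faller(p, 0.25, 1.957, 0), 1.957)
  }
  # extreme negative slope is floored at one fall per faller
  expect_equal(falls_per_faller(0.9, 0.1, 1.5, -10), 1)
})

test_that("falls per faller is linear where the floor does not bind", {
  set.seed(7)
  for (i in 1:25) {
    a <- runif(1, 0.3, 0.5); b <- runif(1, 0.5, 0.9)
    expect_equal(falls_per_faller(a, 0.25, 2, 1.5) + falls_per_faller(b, 0.25, 2, 1.5),
                 2 * falls_per_faller((a + b) / 2, 0.25, 2, 1.5),
                 tolerance = 1e-12)
  }
})

test_that("annual-to-period conversion follows a constant hazard", {
  expect_equal(annual_to_period_prob(0, 0.5), 0)
  expect_equal(annual_to_period_prob(0.37, 1), 0.37)
  expect_equal(annual_to_period_prob(0.2, 0.5), 0.105572809000084,
               tolerance = 1e-12)
  expect_warning(p1 <- annual_to_period_prob(1, 0.5), "degenerate")
  expect_equal(p1, 1)
  expect_error(annual_to_period_prob(1.2, 0.5), "\\[0, 1\\]")
})

test_that("period conversion is strictly monotone and round-trips to 1e-12", {
  set.seed(8)
  p <- sort(runif(50, 0, 0.99))
  for (h in c(0.25, 0.5, 2)) {
    period <- annual_to_period_prob(p, h)
    expect_true(all(diff(period) > 0))
    expect_equal(period_to_annual_prob(period, h), p, tolerance = 1e-12)
  }
  # monotone in the horizon too
  hs <- c(0.1, 0.5, 1, 2)
  expect_true(all(diff(vapply(hs, annual_to_period_prob, 0, p_annual = 0.3)) > 0))
})

test_that("the fall outcome split reproduces the printed 2.56/2.56/2.88%", {
  s <- fall_outcome_split(0.56, 0.08, 0.32, 0.53)
  expect_equal(s[["p_admit_nonfracture"]], 0.0256, tolerance = 1e-12)
  expect_equal(s[["p_admit_nonhip_fracture"]], 0.025568, tolerance = 1e-12)
  expect_equal(s[["p_admit_hip_fracture"]], 0.028832, tolerance = 1e-12)
  expect_equal(round(100 * s[["p_admit_nonfracture"]], 2), 2.56)
  expect_equal(round(100 * s[["p_admit_nonhip_fracture"]], 2), 2.56)
  expect_equal(round(100 * s[["p_admit_hip_fracture"]], 2), 2.88)
  # outpatient-only and no-care are the complements
  expect_equal(s[["p_outpatient"]], 0.48, tolerance = 1e-12)
  expect_equal(s[["p_no_care"]], 0.44, tolerance = 1e-12)

  zero <- fall_outcome_split(0.56, 0, 0.32, 0.53)
  expect_equal(unname(zero[3:5]), c(0, 0, 0))
  expect_error(fall_outcome_split(0.1, 0.2, 0.3, 0.5), "subset")
})

test_that("the fall outcome split always partitions and bounds fall deaths", {
  set.seed(9)
  for (i in 1:100) {
    any_care <- runif(1)
    admit <- runif(1, 0, any_care)
    s <- fall_outcome_split(any_care, admit, runif(1), runif(1))
    expect_equal(sum(s), 1, tolerance = 1e-12)
    expect_equal(sum(s[3:5]), admit, tolerance = 1e-12)
    # per-fall death probability cannot exceed the admission fraction
    fatal <- runif(3)
    expect_lte(sum(s[3:5] * fatal), admit + 1e-15)
  }
})

test_that("employment scaling multiplies the annual rate", {
  expect_equal(scale_rate_by_employment(0.04, 0.243), 0.00972, tolerance = 1e-15)
  expect_equal(scale_rate_by_employment(0, 0.9), 0)
  expect_error(scale_rate_by_employment(1.2, 0.3), "\\[0, 1\\]")
})

test_that("event risk composes baseline, relative effect and horizon", {
  # hand-built: baseline 0.1/yr, relative effect 2, horizon 0.5
  ps <- params_with(baseline_annual_risk.mvc.younger = 0.1, or.mvc.untreated = 2)
  prof <- event_risk("untreated", "mvc", "younger", ps)
  expect_equal(prof$period_probability, 1 - 0.8^0.5, tolerance = 1e-12)
  expect_equal(prof$expected_count_per_capita, prof$period_probability)
  expect_equal(prof$death_probability,
               prof$period_probability * param_value(ps, "fatality.mvc"))

  # untreated falls apply the 1.48 relative risk to the baseline
  base <- param_value(ps, "baseline_annual_risk.fall.older")
  fall <- event_risk("untreated", "fall", "older", ps)
  expect_equal(fall$period_probability,
               annual_to_period_prob(base * 1.48, 0.5), tolerance = 1e-12)

  # zero baseline risk: all-zero profile
  ps0 <- params_with(baseline_annual_risk.wpa.younger = 0)
  for (a in age_groups()) {
    prof0 <- event_risk("lemborexant", "wpa", a, ps0)
    expect_identical(prof0$period_probability, 0)
    expect_identical(prof0$expected_count_per_capita, 0)
    expect_identical(prof0$death_probability, 0)
  }
})

test_that("event risk profiles satisfy their invariants on random fixtures", {
  for (seed in 1:30) {
    ps <- random_parameters(seed)
    for (s in strategies()) {
      for (e in events()) {
        prof <- suppressWarnings(event_risk(s, e, "older", ps))
        expect_gte(prof$period_probability, 0)
        expect_lte(prof$period_probability, 1)
        expect_lte(prof$death_probability, prof$period_probability + 1e-15)
        if (e == "fall") {
          expect_gte(prof$expected_count_per_capita,
                     prof$period_probability - 1e-15)
        }
      }
    }
  }
})

test_that("a composite annual risk above one is clipped with a warning", {
  ps <- params_with(baseline_annual_risk.mvc.younger = 0.5, or.mvc.untreated = 4)
  msgs <- capture_warnings(prof <- event_risk("untreated", "mvc", "younger", ps))
  expect_true(any(grepl("clipped", msgs)))
  expect_equal(prof$period_probability, 1)
})
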