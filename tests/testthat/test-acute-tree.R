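fix <- reference_inputs()

test_that("branch probabilities are the stated complements", {
  pr <- branch_probabilities(fix$arms$ctz_taz$efficacy,
                             fix$arms$ctz_taz$discharge_fraction_if_cured)
  expect_equal(pr$p_to_second, 1 - 0.606 - 0.201)
  expect_equal(pr$p_cure1 + pr$p_die1 + pr$p_to_second, 1)
  expect_equal(pr$p_cure2 + pr$p_die2 + pr$p_longterm_icu, 1)
  expect_equal(pr$p_discharge_given_cure + pr$p_ward_given_cure, 1)

  pr_m <- branch_probabilities(fix$arms$mepm$efficacy,
                               fix$arms$mepm$discharge_fraction_if_cured)
  expect_equal(pr_m$p_to_second, 1 - 0.571 - 0.255)

  eff <- fix$arms$ctz_taz$efficacy
  eff$cure_first <- rwb(1); eff$mort_first <- rwb(0)
  expect_equal(branch_probabilities(
    eff, fix$arms$ctz_taz$discharge_fraction_if_cured)$p_to_second, 0)

  eff$cure_first <- rwb(0.8); eff$mort_first <- rwb(0.3)
  expect_error(branch_probabilities(
    eff, fix$arms$ctz_taz$discharge_fraction_if_cured), "infeasible")
})

test_that("conditional mortality mode multiplies by the non-cure fraction", {
  eff <- fix$arms$mepm$efficacy
  pr <- branch_probabilities(eff, 0.5, conditional = TRUE)
  expect_equal(pr$p_die1, (1 - 0.571) * 0.255)
})

test_that("second-line derivation applies the relative penalties", {
  d <- derive_second_line(0.606, 0.201)
  expect_equal(d[["mort"]], 0.2412)
  expect_equal(d[["cure"]], 0.606 * 0.9)
  expect_equal(derive_second_line(0.571, 0.255)[["mort"]], 0.306)
  expect_equal(derive_second_line(0.5, 0)[["mort"]], 0)
  w <- capture_warnings(d <- derive_second_line(0.5, 0.9))
  expect_true(any(grepl("clamped", w)))
  expect_true(any(grepl("truncated", w)))
  expect_lte(d[["cure"]] + d[["mort"]], 1)
})

test_that("drug, ventilation and adverse-event costing match the fee arithmetic", {
  expect_equal(drug_cost(36414, 8), 291312)
  expect_equal(drug_cost(2589, 8.23), 21307.47)
  expect_equal(drug_cost(36414 + 714, 7), 259896)
  expect_equal(drug_cost(2589 + 714, 7), 23121)

  expect_equal(ventilation_cost(12, "first"), 114000)
  expect_equal(ventilation_cost(13, "first"), 123500)
  expect_equal(ventilation_cost(12, "second"), 97800)
  expect_equal(ventilation_cost(0, "first"), 0)

  ctz_rates <- lapply(fix$arms$ctz_taz$ae_rates, pt_est)
  mep_rates <- lapply(fix$arms$mepm$ae_rates, pt_est)
  costs <- fix$costs$ae_costs
  expect_equal(expected_ae_cost(ctz_rates, costs), 42435.33, tolerance = 1e-6)
  expect_equal(expected_ae_cost(mep_rates, costs), 41887.05, tolerance = 1e-6)
  expect_equal(expected_ae_cost(ctz_rates, costs, include_amk = TRUE,
                                amk_rate = 0.06, amk_cost = 94800),
               48123.33, tolerance = 1e-6)
  expect_equal(expected_ae_cost(mep_rates, costs, include_amk = TRUE,
                                amk_rate = 0.06, amk_cost = 94800),
               47575.05, tolerance = 1e-6)
  expect_equal(expected_ae_cost(list(a = 0, b = 0), list(a = 1e6, b = 1)), 0)
  expect_error(expected_ae_cost(list(a = 0.1), list(b = 5)), "no cost")
})

test_that("adverse-event cost is linear in rates and costs (superposition)", {
  set.seed(42)
  for (i in 1:20) {
    r1 <- as.list(runif(3)); r2 <- as.list(runif(3))
    names(r1) <- names(r2) <- c("a", "b", "c")
    cost <- as.list(runif(3, 0, 1e5)); names(cost) <- names(r1)
    lhs <- expected_ae_cost(Map(function(x, y) (x + y) / 2, r1, r2), cost)
    rhs <- (expected_ae_cost(r1, cost) + expected_ae_cost(r2, cost)) / 2
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("acute QALYs weight time in state by annual utility over 365.25", {
  # single-branch check: 28 ventilated-ICU days at u = -0.39
  probs <- list(p_to_second = 0, p_longterm_icu = 0, p_cure1 = 1, p_die1 = 0,
                p_cure2 = 0, p_die2 = 0,
                p_discharge_given_cure = 1, p_ward_given_cure = 0)
  dur <- fix$arms$ctz_taz$durations
  q <- acute_qaly(dur, probs, fix$utilities, fix$settings)
  expect_equal(q, -0.39 * 28 / 365.25)

  u0 <- fix$utilities; u0$u_icu_vent <- rwb(0)
  expect_equal(acute_qaly(dur, probs, u0, fix$settings), 0)

  dur0 <- lapply(dur, function(x) rwb(0))
  expect_equal(acute_qaly(dur0, probs, fix$utilities, fix$settings), 0)
})

test_that("acute evaluation reproduces the component cost breakdown", {
  ao <- evaluate_acute("ctz_taz", fix)
  b <- ao$cost_breakdown
  expect_equal(b$drug_first, 291312)
  expect_equal(b$drug_second, 259896)
  expect_equal(b$hospitalization_first, 2136960)
  expect_equal(b$hospitalization_second, 350340)
  expect_equal(b$ventilation_first, 114000)
  expect_equal(b$ventilation_second, 97800)
  expect_equal(b$ae_first, 42435.33, tolerance = 1e-6)
  expect_equal(b$ae_second, 48123.33, tolerance = 1e-6)
  expect_equal(b$long_term_icu, 495000)

  bm <- evaluate_acute("mepm", fix)$cost_breakdown
  expect_equal(bm$drug_first, 21307.47)
  expect_equal(bm$drug_second, 23121)
  expect_equal(bm$ventilation_first, 123500)
  expect_equal(bm$ae_first, 41887.05, tolerance = 1e-6)
})

test_that("a forced full-cure-and-discharge path yields a degenerate end state", {
  p <- fix
  p$arms$ctz_taz$efficacy$cure_first <- rwb(1)
  p$arms$ctz_taz$efficacy$mort_first <- rwb(0)
  p$arms$ctz_taz$discharge_fraction_if_cured <- rwb(1)
  ao <- evaluate_acute("ctz_taz", p)
  es <- ao$end_states
  expect_equal(sum(es$probability[es$state == "DischargedAlive"]), 1)
  b <- ao$cost_breakdown
  expect_equal(ao$expected_cost,
               b$drug_first + b$hospitalization_first + b$ventilation_first +
                 b$ae_first)
})

test_that("end-state distribution sums to 1 for random valid inputs", {
  set.seed(7)
  for (i in 1:25) {
    p <- random_valid_params()
    for (arm in c("ctz_taz", "mepm")) {
      es <- evaluate_acute(arm, p)$end_states
      expect_lt(abs(sum(es$probability) - 1), 1e-12)
      expect_true(all(es$probability >= 0))
    }
  }
})

test_that("path-enumeration oracle equals the component-weighted cost", {
  set.seed(11)
  for (i in 1:25) {
    p <- random_valid_params()
    for (arm in c("ctz_taz", "mepm")) {
      oracle <- enumerate_tree_cost(arm, p)
      got <- evaluate_acute(arm, p)$expected_cost
      expect_lt(abs(oracle$prob_total - 1), 1e-12)
      expect_lt(abs(got - oracle$cost) / oracle$cost, 1e-9)
    }
  }
})

test_that("expected cost is monotone in rates, durations and tariffs", {
  base <- evaluate_acute("mepm", fix)$expected_cost
  up <- function(id, v) evaluate_acute("mepm", param_set(fix, id, v))$expected_cost
  expect_gte(up("arms.mepm.durations.admin_days_first", 10), base)
  expect_gte(up("arms.mepm.durations.vent_days_first", 20), base)
  expect_gte(up("costs.drug_daily.mepm", 5000), base)
  expect_gte(up("costs.ae_costs.septic_shock", 7e5), base)
  expect_gte(up("amk_ae.incidence", 0.2), base)
})
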