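fix <- reference_inputs()

test_that("discounting and rate conversion follow their closed forms", {
  expect_equal(discount_factor(3.7, 0), 1)
  expect_equal(discount_factor(1, 0.02), 1 / 1.02)
  expect_equal(discount_factor(5, 0.02), 1 / 1.02^5)
  expect_equal(annual_to_cycle_probability(0, 30), 0)
  expect_equal(annual_to_cycle_probability(1, 30), 1)
  expect_equal(annual_to_cycle_probability(0.02, 30),
               1 - 0.98^(30 / 365.25))
})

flat_spec <- function(q_annual = 0, discount = 0, u = 0.8,
                      horizon_years = 5) {
  sp <- markov_spec(fix)
  sp$life_table <- data.frame(age = 0:200, qx = q_annual)
  sp$discount_rate_annual <- discount
  sp$state_utilities[["DischargedAlive"]] <- u
  sp$horizon_days <- horizon_years * 365.25
  sp
}

test_that("an all-dead cohort accrues nothing", {
  tr <- run_cohort(c(DischargedAlive = 0, InWard = 0, Dead = 1),
                   markov_spec(fix))
  expect_equal(attr(tr, "total_qaly"), 0)
  expect_equal(attr(tr, "total_cost"), 0)
})

test_that("no mortality and no discounting gives utility times horizon", {
  tr <- run_cohort(c(DischargedAlive = 1, InWard = 0, Dead = 0), flat_spec())
  expect_equal(attr(tr, "total_qaly"), 0.8 * 5, tolerance = 1e-12)
})

test_that("constant-hazard run matches an independent summation oracle", {
  sp <- flat_spec(q_annual = 0.02, discount = 0.02)
  tr <- run_cohort(c(DischargedAlive = 1, InWard = 0, Dead = 0), sp)
  # independent oracle: occupancy at cycle start is the survival product,
  # utility accrues per cycle, discounted at the cycle midpoint
  horizon <- 5 * 365.25
  lens <- c(rep(30, floor(horizon / 30)), horizon - 30 * floor(horizon / 30))
  starts <- cumsum(c(0, lens[-length(lens)]))
  q_cyc <- 1 - (1 - 0.02)^(lens / 365.25)
  occ <- cumprod(c(1, (1 - q_cyc)[-length(lens)]))
  oracle <- sum(occ * 0.8 * (lens / 365.25) *
                  (1.02)^(-(starts + lens / 2) / 365.25))
  expect_equal(attr(tr, "total_qaly"), oracle, tolerance = 1e-12)
})

test_that("occupancy is conserved every cycle and Dead is absorbing", {
  set.seed(3)
  for (i in 1:10) {
    p <- random_valid_params()
    sp <- markov_spec(p)
    init <- c(DischargedAlive = 0.55, InWard = 0.25, Dead = 0.2)
    tr <- run_cohort(init, sp, offset_days = runif(1, 0, 200))
    sums <- tr$discharged + tr$ward + tr$dead
    expect_true(all(abs(sums - 1) < 1e-12))
    expect_true(all(diff(tr$dead) >= -1e-15))
  }
})

test_that("the ward month lasts one cycle and applies its mortality once", {
  sp <- flat_spec()  # no background mortality
  sp$ward_mortality <- 0.076
  tr <- run_cohort(c(DischargedAlive = 0, InWard = 1, Dead = 0), sp)
  expect_equal(tr$ward[1], 1)
  expect_equal(tr$ward[2], 0)
  expect_equal(tr$discharged[2], 1 - 0.076)
  expect_equal(tr$dead[nrow(tr)], 0.076)
})

test_that("discounting reduces totals and mortality reduces QALYs monotonically", {
  init <- c(DischargedAlive = 1, InWard = 0, Dead = 0)
  q_undisc <- attr(run_cohort(init, flat_spec(0.02, 0)), "total_qaly")
  q_disc <- attr(run_cohort(init, flat_spec(0.02, 0.02)), "total_qaly")
  expect_lt(q_disc, q_undisc)
  qalys <- sapply(c(0, 0.02, 0.1, 0.3),
                  function(q) attr(run_cohort(init, flat_spec(q, 0.02)),
                                   "total_qaly"))
  expect_true(all(diff(qalys) < 0))
  rates <- sapply(c(0, 0.01, 0.03, 0.08),
                  function(r) attr(run_cohort(init, flat_spec(0.02, r)),
                                   "total_qaly"))
  expect_true(all(diff(rates) < 0))
})

test_that("cohort totals agree with an individual-level microsimulation", {
  sp <- markov_spec(fix)  # Gompertz hazards, 2% discount
  init <- c(DischargedAlive = 0.7, InWard = 0.3, Dead = 0)
  tr_q <- 0.7 * attr(run_cohort(c(DischargedAlive = 1, InWard = 0, Dead = 0),
                                sp, offset_days = 28), "total_qaly") +
    0.3 * attr(run_cohort(c(DischargedAlive = 0, InWard = 1, Dead = 0),
                          sp, offset_days = 28), "total_qaly")

  # microsimulation with the same hazards and accrual rules
  set.seed(202)
  n <- 1e5
  state <- sample(c("D", "W"), n, replace = TRUE, prob = c(0.7, 0.3))
  alive <- rep(TRUE, n)
  horizon <- sp$horizon_days; elapsed <- 28
  qaly <- numeric(n)
  while (elapsed < horizon - 1e-9) {
    len <- min(30, horizon - elapsed)
    cyc_years <- len / 365.25
    disc <- (1 + sp$discount_rate_annual)^(-(elapsed + len / 2) / 365.25)
    u <- ifelse(state == "W", sp$state_utilities[["InWard"]],
                sp$state_utilities[["DischargedAlive"]])
    qaly <- qaly + alive * u * cyc_years * disc
    age <- sp$start_age + elapsed / 365.25
    q_bg <- annual_to_cycle_probability(
      sp$life_table$qx[findInterval(floor(age), sp$life_table$age)], len)
    p_die <- ifelse(state == "W", sp$ward_mortality, q_bg)
    dies <- alive & (runif(n) < p_die)
    alive <- alive & !dies
    state[state == "W"] <- "D"
    elapsed <- elapsed + len
  }
  mc_mean <- mean(qaly)
  mc_se <- sd(qaly) / sqrt(n)
  expect_lt(abs(mc_mean - tr_q), 4 * mc_se)
})

test_that("tree-to-cohort handoff weights entry-time groups by mass", {
  ao <- evaluate_acute("ctz_taz", fix)
  sp <- markov_spec(fix)
  mk <- run_cohort_from_tree(ao$end_states, sp)
  # manual recomposition over offsets
  live <- ao$end_states[ao$end_states$state != "Dead", ]
  manual <- 0
  for (off in unique(live$offset_days)) {
    grp <- live[live$offset_days == off, ]
    mass <- sum(grp$probability)
    init <- c(DischargedAlive = 0, InWard = 0, Dead = 0)
    for (i in seq_len(nrow(grp))) init[[grp$state[i]]] <-
        init[[grp$state[i]]] + grp$probability[i] / mass
    manual <- manual + mass * attr(run_cohort(init, sp, off), "total_qaly")
  }
  expect_equal(mk$total_qaly, manual, tolerance = 1e-12)
  expect_error(run_cohort_from_tree(
    data.frame(state = "Dead", probability = 0.5, offset_days = 0), sp),
    "sum to 1")
})

test_that("a later entry leaves fewer cycles (horizon fixed at model entry)", {
  sp <- flat_spec()
  q0 <- attr(run_cohort(c(DischargedAlive = 1, InWard = 0, Dead = 0), sp, 0),
             "total_qaly")
  q100 <- attr(run_cohort(c(DischargedAlive = 1, InWard = 0, Dead = 0), sp,
                          100), "total_qaly")
  expect_equal(q0 - q100, 0.8 * 100 / 365.25, tolerance = 1e-12)
})
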