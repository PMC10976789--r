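# Random valid parameter sets for property-style tests. Rates are drawn so
# every tree line stays feasible (cure + mortality <= 1); durations, costs
# and utilities stay in their domains.
random_valid_params <- function() {
  p <- reference_inputs()
  for (a in names(p$arms)) {
    cure1 <- runif(1, 0.2, 0.8); mort1 <- runif(1, 0, 1 - cure1)
    cure2 <- runif(1, 0.2, 0.8); mort2 <- runif(1, 0, 1 - cure2)
    p$arms[[a]]$efficacy$cure_first <- rwb(cure1)
    p$arms[[a]]$efficacy$mort_first <- rwb(mort1)
    p$arms[[a]]$efficacy$cure_second <- rwb(cure2)
    p$arms[[a]]$efficacy$mort_second <- rwb(mort2)
    p$arms[[a]]$discharge_fraction_if_cured <- rwb(runif(1))
    p$arms[[a]]$durations$admin_days_first <- rwb(runif(1, 1, 14))
    p$arms[[a]]$durations$icu_los_first <- rwb(runif(1, 5, 40))
    p$arms[[a]]$durations$vent_days_first <- rwb(runif(1, 0, 28))
    p$arms[[a]]$durations$vent_days_second <- rwb(runif(1, 0, 28))
    for (ae in names(p$arms[[a]]$ae_rates))
      p$arms[[a]]$ae_rates[[ae]] <- rwb(runif(1, 0, 0.2))
  }
  p$utilities$u_icu_vent <- rwb(runif(1, -0.5, 0.5))
  p$utilities$u_discharged <- rwb(runif(1, 0.5, 1))
  p$utilities$u_ward <- rwb(runif(1, 0.3, 0.9))
  p$settings$discount_rate_annual <- rwb(runif(1, 0, 0.05))
  p$settings$ward_mortality <- rwb(runif(1, 0, 0.3))
  validate_parameters(p, warn = FALSE)
}

# Independent brute-force oracle for the acute tree: enumerate every
# root-to-leaf path with its probability and the costs incurred along it.
enumerate_tree_cost <- function(arm, params) {
  ao <- evaluate_acute(arm, params)
  pr <- ao$probabilities
  b <- ao$cost_breakdown
  line1 <- b$drug_first + b$hospitalization_first + b$ventilation_first +
    b$ae_first
  line2 <- b$drug_second + b$hospitalization_second + b$ventilation_second +
    b$ae_second
  d <- pr$p_discharge_given_cure
  paths <- rbind(
    c(pr$p_cure1 * d,                line1),
    c(pr$p_cure1 * (1 - d),          line1 + b$long_term_ward),
    c(pr$p_die1,                     line1),
    c(pr$p_to_second * pr$p_cure2 * d,       line1 + line2),
    c(pr$p_to_second * pr$p_cure2 * (1 - d), line1 + line2 + b$long_term_ward),
    c(pr$p_to_second * pr$p_die2,            line1 + line2),
    c(pr$p_to_second * pr$p_longterm_icu,    line1 + line2 + b$long_term_icu)
  )
  list(prob_total = sum(paths[, 1]), cost = sum(paths[, 1] * paths[, 2]))
}
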