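#' Discount factor
#'
#' Present-value weight of a cost or QALY accruing `elapsed` years after
#' model entry, `1 / (1 + rate)^elapsed`. Continuous in elapsed time; the
#' cohort engine evaluates it at cycle midpoints.
#'
#' @param elapsed years since model entry.
#' @param rate annual discount rate (proportion, >= 0).
#' @return the discount factor.
#' @examples
#' discount_factor(1, 0.02)  # 1/1.02
#' @export
discount_factor <- function(elapsed, rate) {
  stopifnot(all(rate >= 0))
  (1 + rate)^(-elapsed)
}

#' Convert an annual probability to a cycle probability
#'
#' Constant-hazard conversion: `1 - (1 - p)^(days/365.25)`.
#'
#' @param p_annual annual probability in \[0, 1\].
#' @param cycle_days cycle length in days.
#' @return per-cycle probability.
#' @examples
#' annual_to_cycle_probability(0.02, 30)
#' @export
annual_to_cycle_probability <- function(p_annual, cycle_days) {
  stopifnot(all(p_annual >= 0), all(p_annual <= 1))
  1 - (1 - p_annual)^(cycle_days / 365.25)
}

lookup_qx <- function(life_table, age) {
  i <- findInterval(floor(age), life_table$age)
  i[i < 1L] <- 1L
  i[i > nrow(life_table)] <- nrow(life_table)
  life_table$qx[i]
}

#' Markov specification for the long-term phase
#'
#' Bundles what the cohort engine needs: cycle length, horizon, discount
#' rate, per-stay ward mortality, cohort starting age, the life table, state
#' utilities and (optional) per-cycle state costs.
#'
#' @param params a `cea_parameters` object.
#' @return list of class `"markov_spec"`.
#' @export
markov_spec <- function(params) {
  s <- params$settings
  structure(list(
    states = c("DischargedAlive", "InWard", "Dead"),
    cycle_length_days = s$cycle_length_days,
    horizon_days = s$horizon_years * 365.25,
    discount_rate_annual = pt_est(s$discount_rate_annual),
    ward_mortality = pt_est(s$ward_mortality),
    start_age = s$cohort_start_age,
    life_table = params$life_table,
    state_utilities = c(DischargedAlive = pt_est(params$utilities$u_discharged),
                        InWard = pt_est(params$utilities$u_ward),
                        Dead = 0),
    state_costs = c(DischargedAlive = 0, InWard = 0, Dead = 0)
  ), class = "markov_spec")
}

#' Propagate a cohort through the long-term Markov model
#'
#' Three states: `DischargedAlive`, `InWard`, `Dead` (absorbing). The ward
#' lasts exactly one cycle: its occupants accrue the ward utility for that
#' cycle, die with the per-stay ward mortality, and survivors move to
#' `DischargedAlive`. Discharged patients die at the age-specific life-table
#' hazard converted to the cycle length; age advances with elapsed time
#' (integer-age lookup). QALYs accrue as start-of-cycle occupancy x annual
#' utility x cycle length in years, discounted at the cycle midpoint measured
#' from model entry (no half-cycle correction). The trace stops when
#' `offset_days + elapsed` reaches the horizon; a fractional final cycle
#' covers the remainder exactly.
#'
#' @param initial named numeric over the three states, summing to 1.
#' @param spec a `"markov_spec"` object (see [markov_spec()]).
#' @param offset_days days already elapsed at entry (acute-phase duration for
#'   this pathway); discounting and the horizon are measured from model
#'   entry, so a later entry leaves fewer cycles.
#' @return object of class `"cohort_trace"`: a data frame (one row per cycle:
#'   `cycle`, `days_start`, `days_end`, occupancy at cycle start in
#'   `discharged`, `ward`, `dead`, and discounted increments `dqaly`,
#'   `dcost`) with attributes `total_qaly`, `total_cost`,
#'   `total_qaly_undiscounted`.
#' @examples
#' sp <- markov_spec(reference_inputs())
#' tr <- run_cohort(c(DischargedAlive = 1, InWard = 0, Dead = 0), sp)
#' attr(tr, "total_qaly")
#' @export
run_cohort <- function(initial, spec, offset_days = 0) {
  states <- spec$states
  occ <- c(DischargedAlive = 0, InWard = 0, Dead = 0)
  occ[names(initial)] <- as.numeric(initial)
  if (abs(sum(occ) - 1) > 1e-9)
    stop("initial state distribution must sum to 1", call. = FALSE)

  remaining <- spec$horizon_days - offset_days
  rows <- list(); tq <- 0; tq_undisc <- 0; tc <- 0
  if (remaining > 1e-9) {
    n_full <- floor(remaining / spec$cycle_length_days)
    lens <- rep(spec$cycle_length_days, n_full)
    frac <- remaining - n_full * spec$cycle_length_days
    if (frac > 1e-9) lens <- c(lens, frac)
    elapsed <- offset_days
    for (t in seq_along(lens)) {
      len <- lens[t]
      cyc_years <- len / 365.25
      mid_years <- (elapsed + len / 2) / 365.25
      disc <- discount_factor(mid_years, spec$discount_rate_annual)

      uq <- sum(occ * spec$state_utilities[names(occ)]) * cyc_years
      dq <- uq * disc
      dc <- sum(occ * spec$state_costs[names(occ)]) * disc
      tq <- tq + dq; tq_undisc <- tq_undisc + uq; tc <- tc + dc
      rows[[t]] <- c(cycle = t, days_start = elapsed, days_end = elapsed + len,
                     discharged = occ[["DischargedAlive"]],
                     ward = occ[["InWard"]], dead = occ[["Dead"]],
                     dqaly = dq, dcost = dc)

      age <- spec$start_age + elapsed / 365.25
      q_bg <- annual_to_cycle_probability(lookup_qx(spec$life_table, age), len)
      died_bg <- occ[["DischargedAlive"]] * q_bg
      # ward lasts one cycle: per-stay mortality applied once, survivors
      # discharged
      ward_mass <- occ[["InWard"]]
      died_ward <- ward_mass * spec$ward_mortality
      occ[["DischargedAlive"]] <- occ[["DischargedAlive"]] - died_bg +
        (ward_mass - died_ward)
      occ[["InWard"]] <- 0
      occ[["Dead"]] <- occ[["Dead"]] + died_bg + died_ward
      elapsed <- elapsed + len
    }
  }
  trace <- if (length(rows)) as.data.frame(do.call(rbind, rows))
  else data.frame(cycle = numeric(), days_start = numeric(),
                  days_end = numeric(), discharged = numeric(),
                  ward = numeric(), dead = numeric(), dqaly = numeric(),
                  dcost = numeric())
  structure(trace, class = c("cohort_trace", "data.frame"),
            total_qaly = tq, total_cost = tc,
            total_qaly_undiscounted = tq_undisc,
            offset_days = offset_days)
}

#' Long-term results for one arm's end-state distribution
#'
#' Runs the cohort engine once per distinct entry time in the acute
#' end-state distribution (pathways leave the acute phase at different
#' elapsed times) and sums mass-weighted discounted totals.
#'
#' @param end_states data frame `state`, `probability`, `offset_days` from
#'   [evaluate_acute()].
#' @param spec a `"markov_spec"` object.
#' @return list with `total_qaly`, `total_cost`, and `traces` (one
#'   `cohort_trace` per entry-time group, with the group mass in attribute
#'   `"mass"`).
#' @export
run_cohort_from_tree <- function(end_states, spec) {
  if (abs(sum(end_states$probability) - 1) > 1e-9)
    stop("end-state distribution must sum to 1", call. = FALSE)
  live <- end_states[end_states$state != "Dead" & end_states$probability > 0, ]
  tq <- 0; tc <- 0; traces <- list()
  for (off in unique(live$offset_days)) {
    grp <- live[live$offset_days == off, ]
    mass <- sum(grp$probability)
    init <- c(DischargedAlive = 0, InWard = 0, Dead = 0)
    for (i in seq_len(nrow(grp)))
      init[[grp$state[i]]] <- init[[grp$state[i]]] + grp$probability[i] / mass
    tr <- run_cohort(init, spec, offset_days = off)
    attr(tr, "mass") <- mass
    tq <- tq + mass * attr(tr, "total_qaly")
    tc <- tc + mass * attr(tr, "total_cost")
    traces[[as.character(off)]] <- tr
  }
  list(total_qaly = tq, total_cost = tc, traces = traces)
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("Cohort trace:", nrow(x), "cycles, entry offset",
      attr(x, "offset_days"), "days\n")
  cat(sprintf("  discounted QALYs: %.5f  discounted cost: %.2f\n",
              attr(x, "total_qaly"), attr(x, "total_cost")))
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more cycles\n")
  invisible(x)
}

#' Write a cohort trace to CSV
#'
#' @param trace a `cohort_trace` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
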