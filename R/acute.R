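#' Branch probabilities of the acute treatment tree
#'
#' First line: a patient is cured, dies, or moves to second-line treatment
#' (the residual). Second line (conditional on entering it): cured, dies, or
#' remains in long-term ICU care. Cured patients on either line are
#' discharged home or transferred to the general ward.
#'
#' Mortality is read as a marginal proportion of all patients entering the
#' line (the trial reports all-cause mortality over all randomized patients).
#' With `conditional = TRUE` it is instead read as conditional on non-cure,
#' i.e. `p_die = (1 - cure) * mort`.
#'
#' @param eff arm efficacy list with `rwb` entries `cure_first`, `mort_first`,
#'   `cure_second`, `mort_second`.
#' @param discharge_fraction probability a cured patient is discharged home
#'   (the complement is transferred to the general ward).
#' @param conditional interpret mortality as conditional on non-cure.
#' @return list of class `"branch_probs"`: `p_cure1`, `p_die1`, `p_to_second`,
#'   `p_cure2`, `p_die2`, `p_longterm_icu`, `p_discharge_given_cure`,
#'   `p_ward_given_cure`.
#' @examples
#' p <- reference_inputs()
#' branch_probabilities(p$arms$ctz_taz$efficacy,
#'                      pt_est(p$arms$ctz_taz$discharge_fraction_if_cured))
#' @export
branch_probabilities <- function(eff, discharge_fraction,
                                 conditional = FALSE) {
  line <- function(cure, mort) {
    cure <- pt_est(cure); mort <- pt_est(mort)
    die <- if (conditional) (1 - cure) * mort else mort
    if (cure + die > 1 + 1e-12)
      stop("infeasible efficacy: cure + mortality > 1 (",
           cure, " + ", die, ")", call. = FALSE)
    c(cure = cure, die = die, residual = max(0, 1 - cure - die))
  }
  l1 <- line(eff$cure_first, eff$mort_first)
  l2 <- line(eff$cure_second, eff$mort_second)
  d <- pt_est(discharge_fraction)
  structure(list(
    p_cure1 = l1[["cure"]], p_die1 = l1[["die"]],
    p_to_second = l1[["residual"]],
    p_cure2 = l2[["cure"]], p_die2 = l2[["die"]],
    p_longterm_icu = l2[["residual"]],
    p_discharge_given_cure = d, p_ward_given_cure = 1 - d
  ), class = "branch_probs")
}

#' Derive second-line efficacy from first-line rates
#'
#' The second-line regimen (first-line drug plus amikacin) is assumed as
#' effective as the first line, penalized for the burden of first-line
#' failure: cure reduced by a relative fraction, mortality increased by a
#' relative fraction. Derived rates falling outside \[0, 1\] are clamped with
#' a warning.
#'
#' @param cure_first,mort_first first-line rates in \[0, 1\].
#' @param cure_reduction relative cure reduction (default 0.10).
#' @param mort_increase relative mortality increase (default 0.20).
#' @return named numeric `c(cure=, mort=)`.
#' @examples
#' derive_second_line(0.606, 0.201)  # cure 0.5454, mort 0.2412
#' @export
derive_second_line <- function(cure_first, mort_first,
                               cure_reduction = 0.10, mort_increase = 0.20) {
  cure_first <- pt_est(cure_first); mort_first <- pt_est(mort_first)
  stopifnot(cure_first >= 0, cure_first <= 1, mort_first >= 0, mort_first <= 1)
  cure <- cure_first * (1 - cure_reduction)
  mort <- mort_first * (1 + mort_increase)
  if (cure < 0 || cure > 1 || mort < 0 || mort > 1) {
    warning("derived second-line rate clamped to [0, 1]")
    cure <- min(1, max(0, cure)); mort <- min(1, max(0, mort))
  }
  if (cure + mort > 1) {
    warning("derived second-line cure + mortality > 1; mortality truncated")
    mort <- 1 - cure
  }
  c(cure = cure, mort = mort)
}

#' Drug cost of a treatment course
#'
#' Daily tariff times administration duration. For the second line, pass the
#' summed daily tariff of the first-line drug plus amikacin.
#'
#' @param daily_cost yen per day.
#' @param duration days of administration.
#' @return yen.
#' @examples
#' drug_cost(36414, 8)        # 291312
#' drug_cost(36414 + 714, 7)  # 259896
#' @export
drug_cost <- function(daily_cost, duration) {
  daily_cost <- pt_est(daily_cost); duration <- pt_est(duration)
  stopifnot(daily_cost >= 0, duration >= 0)
  daily_cost * duration
}

#' Mechanical-ventilation cost
#'
#' The fee schedule bills ventilation at a higher daily tariff through day 14
#' and a lower one from day 15. First-line ventilation falls in the early
#' window; second-line ventilation days count cumulatively past day 14 and
#' are billed at the late tariff.
#'
#' @param days ventilated days in the phase.
#' @param phase `"first"` or `"second"`.
#' @param early,late daily tariffs (yen) for the two windows.
#' @return yen.
#' @examples
#' ventilation_cost(12, "first")   # 114000
#' ventilation_cost(12, "second")  # 97800
#' @export
ventilation_cost <- function(days, phase = c("first", "second"),
                             early = 9500, late = 8150) {
  phase <- match.arg(phase)
  days <- pt_est(days)
  stopifnot(days >= 0)
  days * if (phase == "first") pt_est(early) else pt_est(late)
}

#' Expected adverse-event treatment cost
#'
#' Sum over events of incidence times per-event treatment cost; optionally
#' adds the amikacin-attributable event (second line only).
#'
#' @param ae_rates named list/vector of incidences in \[0, 1\].
#' @param ae_costs named list/vector of per-event costs (yen); must cover
#'   every named rate.
#' @param include_amk add the amikacin adverse event.
#' @param amk_rate,amk_cost amikacin event incidence and per-event cost.
#' @return yen (expected, per patient entering the line).
#' @examples
#' expected_ae_cost(list(a = 0.036, b = 0.039), list(a = 504885, b = 504885))
#' @export
expected_ae_cost <- function(ae_rates, ae_costs, include_amk = FALSE,
                             amk_rate = 0, amk_cost = 0) {
  rates <- vapply(ae_rates, pt_est, numeric(1))
  if (any(rates < 0 | rates > 1)) stop("adverse-event rate outside [0, 1]")
  missing <- setdiff(names(rates), names(ae_costs))
  if (length(missing))
    stop("adverse event with a rate but no cost: ",
         paste(missing, collapse = ", "), call. = FALSE)
  costs <- vapply(ae_costs[names(rates)], pt_est, numeric(1))
  total <- sum(rates * costs)
  if (include_amk) total <- total + pt_est(amk_rate) * pt_est(amk_cost)
  total
}

days_per_month <- function(settings) settings$cycle_length_days

#' Acute-phase quality-adjusted life-years
#'
#' Time in each acute state weighted by its annual utility and converted at
#' 365.25 days/year: first-line ICU days (all patients) and the 21 additional
#' second-line ICU days (entrants) at the ventilated-ICU utility, the
#' terminal ICU month of patients uncured on second line at the same utility,
#' and — when `include_ward` — the general-ward month of ward-transferred
#' cured patients at the ward utility. In the composed pipeline the ward
#' month is accrued (discounted) by the cohort engine instead, so
#' [evaluate_acute()] calls this with `include_ward = FALSE`.
#'
#' Undiscounted: the acute phase falls inside the first model year.
#'
#' @param durations arm durations list (see [reference_inputs()]).
#' @param probs a `"branch_probs"` object.
#' @param utilities utilities list (`u_icu_vent`, `u_discharged`, `u_ward`).
#' @param settings global settings (month length; terminal ICU months).
#' @param include_ward include the ward month at `u_ward`.
#' @return QALYs (may be negative: the ventilated-ICU utility is below zero).
#' @export
acute_qaly <- function(durations, probs, utilities,
                       settings = reference_inputs()$settings,
                       include_ward = TRUE) {
  u_icu <- pt_est(utilities$u_icu_vent)
  month <- days_per_month(settings)
  icu1 <- pt_est(durations$icu_los_first)
  icu2 <- pt_est(durations$icu_los_second_additional)
  q <- u_icu * icu1 / 365.25
  q <- q + probs$p_to_second * u_icu * icu2 / 365.25
  q <- q + probs$p_to_second * probs$p_longterm_icu *
    u_icu * settings$terminal_icu_months * month / 365.25
  if (include_ward) {
    p_ward <- total_cure(probs) * probs$p_ward_given_cure
    q <- q + p_ward * pt_est(utilities$u_ward) *
      settings$ward_stay_months * month / 365.25
  }
  q
}

total_cure <- function(probs) probs$p_cure1 + probs$p_to_second * probs$p_cure2

#' Evaluate the acute decision tree for one arm
#'
#' Composes branch probabilities, component costs and acute QALYs, and
#' produces the end-of-acute-phase state distribution (with elapsed-time
#' offsets in days) handed to the Markov engine.
#'
#' Costing convention: every patient entering a line incurs that line's full
#' drug, hospitalization, ventilation and expected adverse-event cost (the
#' same administration duration applies to cured and uncured patients);
#' second-line components are weighted by the probability of entering the
#' second line; long-term ICU care by the probability of being uncured on
#' second line; long-term ward care by the probability of a cured patient
#' going to the ward.
#'
#' @param arm `"ctz_taz"` or `"mepm"`.
#' @param params a `cea_parameters` object.
#' @return object of class `"acute_outcome"`: `probabilities`,
#'   `cost_breakdown` (unweighted per-line components, yen),
#'   `component_weights`, `expected_cost` (weighted total, yen), `acute_qaly`,
#'   and `end_states` (data frame `state`, `probability`, `offset_days`).
#' @examples
#' evaluate_acute("ctz_taz", reference_inputs())
#' @export
evaluate_acute <- function(arm, params) {
  a <- params$arms[[arm]]
  if (is.null(a)) stop("unknown arm: ", arm)
  s <- params$settings
  probs <- branch_probabilities(a$efficacy, a$discharge_fraction_if_cured,
                                conditional = isTRUE(s$mortality_conditional))
  if (isTRUE(s$use_derived_second_line)) {
    d2 <- derive_second_line(a$efficacy$cure_first, a$efficacy$mort_first,
                             s$second_line_cure_reduction,
                             s$second_line_mort_increase)
    eff <- a$efficacy
    eff$cure_second <- rwb(d2[["cure"]])
    eff$mort_second <- rwb(d2[["mort"]])
    probs <- branch_probabilities(eff, a$discharge_fraction_if_cured,
                                  conditional = isTRUE(s$mortality_conditional))
  }

  drug1_daily <- pt_est(params$costs$drug_daily[[arm]])
  amk_daily <- pt_est(params$costs$drug_daily$amk)
  breakdown <- list(
    drug_first = drug_cost(drug1_daily, a$durations$admin_days_first),
    drug_second = drug_cost(drug1_daily + amk_daily,
                            a$durations$admin_days_second),
    hospitalization_first = pt_est(a$hospitalization_first),
    hospitalization_second = pt_est(a$hospitalization_second),
    ventilation_first = ventilation_cost(a$durations$vent_days_first, "first",
                                         params$costs$vent_daily_early,
                                         params$costs$vent_daily_late),
    ventilation_second = ventilation_cost(a$durations$vent_days_second,
                                          "second",
                                          params$costs$vent_daily_early,
                                          params$costs$vent_daily_late),
    ae_first = expected_ae_cost(a$ae_rates, params$costs$ae_costs),
    ae_second = expected_ae_cost(a$ae_rates, params$costs$ae_costs,
                                 include_amk = TRUE,
                                 amk_rate = params$amk_ae$incidence,
                                 amk_cost =
                                   params$costs$ae_costs[[params$amk_ae$name]]),
    long_term_icu = pt_est(params$costs$long_term_icu),
    long_term_ward = pt_est(params$costs$long_term_ward)
  )

  p2 <- probs$p_to_second
  p_ward <- total_cure(probs) * probs$p_ward_given_cure
  weights <- list(
    drug_first = 1, drug_second = p2,
    hospitalization_first = 1, hospitalization_second = p2,
    ventilation_first = 1, ventilation_second = p2,
    ae_first = 1, ae_second = p2,
    long_term_icu = p2 * probs$p_longterm_icu,
    long_term_ward = p_ward
  )
  expected_cost <- sum(unlist(breakdown) * unlist(weights)[names(breakdown)])

  month <- days_per_month(s)
  icu1 <- pt_est(a$durations$icu_los_first)
  icu2 <- pt_est(a$durations$icu_los_second_additional)
  d <- probs$p_discharge_given_cure
  end_states <- data.frame(
    state = c("DischargedAlive", "InWard", "DischargedAlive", "InWard",
              "Dead", "Dead", "Dead"),
    probability = c(probs$p_cure1 * d,
                    probs$p_cure1 * (1 - d),
                    p2 * probs$p_cure2 * d,
                    p2 * probs$p_cure2 * (1 - d),
                    probs$p_die1,
                    p2 * probs$p_die2,
                    p2 * probs$p_longterm_icu),
    offset_days = c(icu1, icu1,
                    icu1 + icu2, icu1 + icu2,
                    icu1, icu1 + icu2,
                    icu1 + icu2 + s$terminal_icu_months * month),
    stringsAsFactors = FALSE
  )

  structure(list(
    arm = arm, probabilities = probs,
    cost_breakdown = breakdown, component_weights = weights,
    expected_cost = expected_cost,
    acute_qaly = acute_qaly(a$durations, probs, params$utilities, s,
                            include_ward = FALSE),
    end_states = end_states
  ), class = "acute_outcome")
}

#' @export
print.acute_outcome <- function(x, ...) {
  cat("Acute-phase outcome, arm:", x$arm, "\n")
  cat(sprintf("  expected acute cost : %12.2f yen\n", x$expected_cost))
  cat(sprintf("  acute QALYs         : %12.5f\n", x$acute_qaly))
  p <- x$probabilities
  cat(sprintf("  P(cure 1st) %.3f  P(die 1st) %.3f  P(2nd line) %.3f\n",
              p$p_cure1, p$p_die1, p$p_to_second))
  invisible(x)
}

#' Export a cost breakdown table
#'
#' One row per cost component and arm, with the unweighted per-line cost, the
#' branch-occupancy weight, and the weighted expected cost.
#'
#' @param params a `cea_parameters` object.
#' @param path optional CSV path; when given, the table is also written there.
#' @return data frame with columns `component`, `arm`, `cost`, `weight`,
#'   `expected_cost`.
#' @export
cost_breakdown_table <- function(params, path = NULL) {
  rows <- lapply(names(params$arms), function(arm) {
    ao <- evaluate_acute(arm, params)
    data.frame(component = names(ao$cost_breakdown), arm = arm,
               cost = unlist(ao$cost_breakdown, use.names = FALSE),
               weight = unlist(ao$component_weights[names(ao$cost_breakdown)],
                               use.names = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$expected_cost <- out$cost * out$weight
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
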