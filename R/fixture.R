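#' Built-in reference parameter set
#'
#' The package's reference inputs for the CTZ/TAZ-versus-MEPM comparison in
#' ventilated HABP/VABP from the Japanese payer perspective: trial-derived
#' efficacy and all-cause mortality with 95% bounds, administration durations,
#' ICU length of stay and ventilation days, adverse-event incidences, 2022
#' fee-schedule costs (daily drug tariffs, two-tier ventilation tariff,
#' per-event adverse-event costs, per-arm hospitalization, long-term ICU/ward
#' care), published utility weights, and the global settings (5-year horizon,
#' 30-day cycles, 2% annual discount, 5,000,000 yen/QALY willingness-to-pay).
#'
#' Two published bound sets place the point estimate outside its own interval
#' (CTZ/TAZ first- and second-line cure); they are kept as printed and
#' recorded in the `"bound_anomalies"` attribute rather than silently fixed.
#' The CTZ/TAZ first-line cure point estimate is 60.6% (the value used in the
#' published base-case breakdown); its interval is the printed (61.0, 72.0).
#'
#' The life table is the package's synthetic Gompertz stand-in
#' ([make_life_table()]); replace it via the configuration file to use
#' official vital statistics.
#'
#' @return a validated `cea_parameters` object.
#' @examples
#' p <- reference_inputs()
#' pt_est(p$costs$drug_daily$ctz_taz)  # 36414 yen/day
#' @export
reference_inputs <- function() {
  arms <- list(
    ctz_taz = list(
      label = "CTZ/TAZ",
      efficacy = list(
        cure_first  = rwb(0.606, 0.610, 0.720),
        mort_first  = rwb(0.201, 0.200, 0.310),
        cure_second = rwb(0.568, 0.571, 0.692),
        mort_second = rwb(0.241, 0.240, 0.372)
      ),
      discharge_fraction_if_cured = rwb(0.506),
      durations = list(
        admin_days_first          = rwb(8,    7.64, 8.36),
        admin_days_second         = rwb(7,    4,    10),
        icu_los_first             = rwb(28,   16,   28),
        icu_los_second_additional = rwb(21,   20,   23),
        vent_days_first           = rwb(12,   5,    28),
        vent_days_second          = rwb(12,   5,    28)
      ),
      ae_rates = list(
        septic_shock          = rwb(0.036),
        multiorgan_failure    = rwb(0.039),
        acute_cardiac_failure = rwb(0.025)
      ),
      hospitalization_first  = rwb(2136960),
      hospitalization_second = rwb(350340)
    ),
    mepm = list(
      label = "MEPM",
      efficacy = list(
        cure_first  = rwb(0.571, 0.490, 0.750),
        mort_first  = rwb(0.255, 0.120, 0.280),
        cure_second = rwb(0.528, 0.439, 0.725),
        mort_second = rwb(0.306, 0.144, 0.336)
      ),
      discharge_fraction_if_cured = rwb(0.567),
      durations = list(
        admin_days_first          = rwb(8.23, 7.86, 8.6),
        admin_days_second         = rwb(7,    4,    10),
        icu_los_first             = rwb(24,   15,   28),
        icu_los_second_additional = rwb(21,   20,   23),
        vent_days_first           = rwb(13,   6,    28),
        vent_days_second          = rwb(12,   5,    28)
      ),
      ae_rates = list(
        septic_shock          = rwb(0.047),
        multiorgan_failure    = rwb(0.028),
        acute_cardiac_failure = rwb(0.022)
      ),
      hospitalization_first  = rwb(2063280),
      hospitalization_second = rwb(358020)
    )
  )

  costs <- list(
    drug_daily = list(
      ctz_taz = rwb(36414),
      mepm    = rwb(2589),
      amk     = rwb(714)
    ),
    vent_daily_early = rwb(9500),   # through day 14
    vent_daily_late  = rwb(8150),   # day 15 onward
    ae_costs = list(
      septic_shock          = rwb(504885, 504885, 740757),
      multiorgan_failure    = rwb(504885, 504885, 740757),
      acute_cardiac_failure = rwb(182758, 182758, 189860),
      acute_renal_failure   = rwb(94800)
    ),
    long_term_icu  = rwb(495000),
    long_term_ward = rwb(495000)
  )

  amk_ae <- list(name = "acute_renal_failure",
                 incidence = rwb(0.060, 0.000, 0.276))

  utilities <- list(
    u_icu_vent   = rwb(-0.39, -0.402, 0.30),
    u_discharged = rwb(0.80,  0.66,   1.00),
    u_ward       = rwb(0.77,  0.43,   0.82)
  )

  settings <- list(
    horizon_years              = 5,
    cycle_length_days          = 30,
    discount_rate_annual       = rwb(0.02, 0, 0.04),
    wtp                        = 5e6,
    cohort_start_age           = 65,
    ward_mortality             = rwb(0.076),
    second_line_cure_reduction = 0.10,
    second_line_mort_increase  = 0.20,
    use_derived_second_line    = FALSE,
    mortality_conditional      = FALSE,
    ward_stay_months           = 1,
    terminal_icu_months        = 1
  )

  cea_parameters(arms = arms, costs = costs, amk_ae = amk_ae,
                 utilities = utilities, settings = settings,
                 life_table = make_life_table())
}
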