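#' Assemble and validate a model parameter set
#'
#' The complete input set for one two-arm comparison: per-arm efficacy,
#' durations, adverse-event incidences and hospitalization costs; shared drug,
#' ventilation, adverse-event and long-term-care costs; utilities; global
#' settings (horizon, cycle length, discount rate, willingness-to-pay, cohort
#' starting age, ward mortality, second-line derivation factors); and an
#' age-indexed life table of annual death probabilities.
#'
#' @param arms named list with elements `ctz_taz` and `mepm`, each holding
#'   `efficacy`, `discharge_fraction_if_cured`, `durations`, `ae_rates`,
#'   `hospitalization_first`, `hospitalization_second` (see
#'   [reference_inputs()] for the full shape).
#' @param costs shared cost inputs (daily drug tariffs, two-tier ventilation
#'   tariff, adverse-event unit costs, long-term ICU/ward care).
#' @param amk_ae amikacin adverse-event profile (name + incidence).
#' @param utilities annual utility weights for the three health states.
#' @param settings global settings list.
#' @param life_table data frame with columns `age` and `qx` (annual death
#'   probability), 1-year steps.
#' @param validate run [validate_parameters()] before returning.
#' @return an object of class `"cea_parameters"`.
#' @seealso [reference_inputs()], [load_parameters()], [save_parameters()]
#' @export
cea_parameters <- function(arms, costs, amk_ae, utilities, settings,
                           life_table, validate = TRUE) {
  x <- structure(
    list(arms = arms, costs = costs, amk_ae = amk_ae, utilities = utilities,
         settings = settings, life_table = life_table),
    class = "cea_parameters")
  if (validate) x <- validate_parameters(x, warn = FALSE)
  x
}

#' @export
print.cea_parameters <- function(x, ...) {
  cat("Two-arm cost-effectiveness parameter set\n")
  cat("  arms:", paste(names(x$arms), collapse = ", "), "\n")
  cat("  horizon:", x$settings$horizon_years, "years;",
      "cycle:", x$settings$cycle_length_days, "days;",
      "discount:", 100 * pt_est(x$settings$discount_rate_annual), "%/yr\n")
  cat("  WTP:", format(x$settings$wtp, big.mark = ","), "yen/QALY;",
      "start age:", x$settings$cohort_start_age, "\n")
  cat("  life table ages:", min(x$life_table$age), "-", max(x$life_table$age), "\n")
  an <- attr(x, "bound_anomalies")
  if (length(an)) cat("  bound anomalies (value outside printed interval):\n",
                      paste("   -", an, collapse = "\n"), "\n")
  invisible(x)
}

chk_range <- function(v, lo, hi, what, errs) {
  bad <- v[is.finite(v) & (v < lo | v > hi)]
  if (length(bad)) c(errs, paste0(what, " outside [", lo, ", ", hi, "]: ",
                                  paste(format(bad), collapse = ", ")))
  else errs
}

#' Validate a parameter set
#'
#' Checks every structural invariant: probabilities and their bounds in
#' \[0, 1\], non-negative costs and durations, per-line `cure + mortality <= 1`
#' (the residual is the next branch), utility domains (\[0, 1\] for the two
#' alive-out-of-ICU states, \[-1, 1\] for the ventilated-ICU state), settings
#' ranges, and life-table coverage of `[start_age, start_age + horizon]`.
#'
#' A point estimate lying outside its own printed interval is *recorded* (and
#' optionally warned about) rather than rejected, because the source tables
#' contain typographically ambiguous bounds.
#'
#' @param params a `cea_parameters` object.
#' @param warn emit a consolidated warning for bound anomalies.
#' @return `params`, invisibly, with attribute `"bound_anomalies"` set.
#' @export
validate_parameters <- function(params, warn = TRUE) {
  errs <- character(); anomalies <- character()

  note_anom <- function(x, id) {
    if (inherits(x, "rwb")) {
      v <- x[["value"]]
      if ((is.finite(x[["lower"]]) && v < x[["lower"]]) ||
          (is.finite(x[["upper"]]) && v > x[["upper"]]))
        anomalies <<- c(anomalies, id)
    }
  }
  all3 <- function(x) if (inherits(x, "rwb")) x[is.finite(x)] else as.numeric(x)

  if (!all(c("ctz_taz", "mepm") %in% names(params$arms)))
    errs <- c(errs, "both arms (ctz_taz, mepm) must be present")

  for (a in names(params$arms)) {
    arm <- params$arms[[a]]
    eff <- arm$efficacy
    for (nm in c("cure_first", "mort_first", "cure_second", "mort_second")) {
      errs <- chk_range(all3(eff[[nm]]), 0, 1,
                        paste0("arms.", a, ".efficacy.", nm), errs)
      note_anom(eff[[nm]], paste0("arms.", a, ".efficacy.", nm))
    }
    if (pt_est(eff$cure_first) + pt_est(eff$mort_first) > 1)
      errs <- c(errs, paste0("arm ", a, ": first-line cure + mortality > 1"))
    if (pt_est(eff$cure_second) + pt_est(eff$mort_second) > 1)
      errs <- c(errs, paste0("arm ", a, ": second-line cure + mortality > 1"))
    errs <- chk_range(all3(arm$discharge_fraction_if_cured), 0, 1,
                      paste0("arms.", a, ".discharge_fraction_if_cured"), errs)
    for (nm in names(arm$durations)) {
      v <- all3(arm$durations[[nm]])
      if (any(v < 0)) errs <- c(errs, paste0("arms.", a, ".durations.", nm,
                                             " negative"))
      note_anom(arm$durations[[nm]], paste0("arms.", a, ".durations.", nm))
    }
    for (nm in names(arm$ae_rates)) {
      errs <- chk_range(all3(arm$ae_rates[[nm]]), 0, 1,
                        paste0("arms.", a, ".ae_rates.", nm), errs)
    }
    for (nm in c("hospitalization_first", "hospitalization_second")) {
      if (pt_est(arm[[nm]]) < 0) errs <- c(errs, paste0("arms.", a, ".", nm,
                                                    " negative"))
    }
  }

  cost_leaves <- c(lapply(params$costs$drug_daily, identity),
                   list(vent_daily_early = params$costs$vent_daily_early,
                        vent_daily_late  = params$costs$vent_daily_late,
                        long_term_icu    = params$costs$long_term_icu,
                        long_term_ward   = params$costs$long_term_ward),
                   params$costs$ae_costs)
  for (nm in names(cost_leaves)) {
    if (any(all3(cost_leaves[[nm]]) < 0))
      errs <- c(errs, paste0("cost ", nm, " negative"))
  }

  errs <- chk_range(all3(params$amk_ae$incidence), 0, 1, "amk_ae.incidence", errs)
  errs <- chk_range(all3(params$utilities$u_discharged), 0, 1,
                    "utilities.u_discharged", errs)
  errs <- chk_range(all3(params$utilities$u_ward), 0, 1, "utilities.u_ward", errs)
  errs <- chk_range(all3(params$utilities$u_icu_vent), -1, 1,
                    "utilities.u_icu_vent", errs)

  s <- params$settings
  if (s$horizon_years <= 0) errs <- c(errs, "settings.horizon_years must be > 0")
  if (s$cycle_length_days <= 0) errs <- c(errs, "settings.cycle_length_days must be > 0")
  errs <- chk_range(all3(s$discount_rate_annual), 0, 1,
                    "settings.discount_rate_annual", errs)
  errs <- chk_range(all3(s$ward_mortality), 0, 1, "settings.ward_mortality", errs)
  if (s$wtp < 0) errs <- c(errs, "settings.wtp must be >= 0")

  lt <- params$life_table
  if (!is.data.frame(lt) || !all(c("age", "qx") %in% names(lt)))
    errs <- c(errs, "life_table must be a data frame with columns age, qx")
  else {
    errs <- chk_range(lt$qx, 0, 1, "life_table.qx", errs)
    need <- c(s$cohort_start_age, s$cohort_start_age + s$horizon_years)
    if (min(lt$age) > need[1] || max(lt$age) < need[2])
      errs <- c(errs, sprintf(
        "life_table must cover ages %g-%g (has %g-%g)",
        need[1], need[2], min(lt$age), max(lt$age)))
  }

  if (length(errs))
    stop("invalid parameter set:\n", paste("  -", errs, collapse = "\n"),
         call. = FALSE)
  if (warn && length(anomalies))
    warning("point estimate outside its printed interval for: ",
            paste(anomalies, collapse = ", "), call. = FALSE)
  attr(params, "bound_anomalies") <- anomalies
  invisible(params)
}

# ---- serialization ----------------------------------------------------------

rwb_to_plain <- function(x) {
  out <- list(value = unname(x[["value"]]))
  if (is.finite(x[["lower"]])) out$lower <- unname(x[["lower"]])
  if (is.finite(x[["upper"]])) out$upper <- unname(x[["upper"]])
  out
}

plain_to_rwb <- function(x) {
  rwb(x$value,
      if (is.null(x$lower)) NA_real_ else x$lower,
      if (is.null(x$upper)) NA_real_ else x$upper)
}

to_plain <- function(node) {
  if (inherits(node, "rwb")) return(rwb_to_plain(node))
  if (is.data.frame(node)) return(as.list(node))
  if (is.list(node)) return(lapply(node, to_plain))
  node
}

is_rwb_plain <- function(x) {
  is.list(x) && !is.null(x$value) &&
    all(names(x) %in% c("value", "lower", "upper"))
}

#' Write a parameter set to a configuration file
#'
#' YAML by default; `.json` extension selects JSON. Rates are stored as
#' proportions, money in yen, durations in days. The file round-trips through
#' [load_parameters()] to an identical object.
#'
#' @param params a `cea_parameters` object.
#' @param path output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_parameters <- function(params, path) {
  plain <- to_plain(unclass(params))
  plain$units <- list(rates = "proportion")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(plain, path, precision = 15L)
  }
  invisible(path)
}

is_rate_path <- function(id) {
  grepl("(^|\\.)efficacy\\.|(^|\\.)ae_rates\\.|incidence$|discharge_fraction_if_cured$|ward_mortality$",
        id)
}

merge_into <- function(template, user, prefix = "") {
  if (is_rwb_plain(user) || !is.list(user) || !is.list(template))
    return(user)
  extra <- setdiff(names(user), names(template))
  if (length(extra))
    stop("unknown configuration key(s): ",
         paste(ifelse(nzchar(prefix), paste(prefix, extra, sep = "."), extra),
               collapse = ", "), call. = FALSE)
  for (k in names(user)) {
    template[[k]] <- merge_into(template[[k]], user[[k]],
                                if (nzchar(prefix)) paste(prefix, k, sep = ".")
                                else k)
  }
  template
}

rehydrate <- function(node) {
  if (is_rwb_plain(node)) return(plain_to_rwb(node))
  if (is.list(node)) for (k in names(node)) node[[k]] <- rehydrate(node[[k]])
  node
}

scale_rate_leaves <- function(node, sc, prefix = "") {
  if (is_rwb_plain(node)) {
    if (is_rate_path(prefix)) {
      node$value <- node$value * sc
      if (!is.null(node$lower)) node$lower <- node$lower * sc
      if (!is.null(node$upper)) node$upper <- node$upper * sc
    }
    return(node)
  }
  if (is.list(node)) {
    for (k in names(node))
      node[[k]] <- scale_rate_leaves(node[[k]], sc,
                                     if (nzchar(prefix))
                                       paste(prefix, k, sep = ".") else k)
  }
  node
}

#' Read a parameter set from a configuration file
#'
#' Reads YAML (or JSON, by extension), validates the schema against the
#' built-in template, fills any missing optional keys with the built-in
#' defaults, and rejects unknown keys by name. An optional top-level
#' `units: {rates: percent}` key declares that rate-type entries (efficacy,
#' adverse-event incidences, discharge fractions, ward mortality) are given
#' in percent; internally everything is a proportion.
#'
#' @param path configuration file path.
#' @return a validated `cea_parameters` object.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  else yaml::read_yaml(path)

  rate_scale <- 1
  if (!is.null(raw$units)) {
    u <- raw$units$rates
    if (!is.null(u)) {
      if (!u %in% c("proportion", "percent"))
        stop("units.rates must be 'proportion' or 'percent'", call. = FALSE)
      if (u == "percent") rate_scale <- 1 / 100
    }
    raw$units <- NULL
  }
  # scale only what the file itself provides; template defaults are already
  # proportions
  if (rate_scale != 1) raw <- scale_rate_leaves(raw, rate_scale)

  template <- to_plain(unclass(reference_inputs()))
  merged <- merge_into(template, raw)
  merged <- rehydrate(merged)
  merged$life_table <- data.frame(age = as.numeric(merged$life_table$age),
                                  qx = as.numeric(merged$life_table$qx))
  params <- structure(merged, class = "cea_parameters")
  validate_parameters(params, warn = TRUE)
}
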