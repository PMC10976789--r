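#' Synthetic Gompertz life table
#'
#' The long-term phase needs an age-indexed table of annual death
#' probabilities. The package ships a parametric Gompertz stand-in (it is a
#' synthetic construction, not national vital statistics): the annual hazard
#' at age `a` is `alpha * exp(beta * (a - age_min))`, so the annual death
#' probability is
#' `q(a) = 1 - exp(-alpha * exp(beta * (a - age_min)))`.
#'
#' Defaults give roughly a 1% annual death probability at age 65 with a
#' log-hazard slope of 0.09 per year — the order of magnitude of a
#' high-income-country life table at those ages.
#'
#' @param alpha baseline annual hazard at `age_min` (> 0).
#' @param beta log-hazard slope per year of age.
#' @param age_min,age_max covered age range (1-year steps).
#' @return data frame with columns `age`, `qx`.
#' @examples
#' lt <- make_life_table()
#' head(lt)
#' @export
make_life_table <- function(alpha = 0.01, beta = 0.09,
                            age_min = 60, age_max = 110) {
  stopifnot(alpha > 0, age_max >= age_min)
  age <- seq(age_min, age_max)
  qx <- 1 - exp(-alpha * exp(beta * (age - age_min)))
  if (any(qx >= 1)) stop("life table: annual death probability reaches 1 ",
                         "within the requested age range")
  data.frame(age = age, qx = qx)
}

#' Write a life table to CSV
#'
#' Two columns (`age`, annual death probability `qx`), consumable by the
#' configuration loader.
#'
#' @param life_table data frame with columns `age`, `qx`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(life_table, path) {
  utils::write.csv(life_table, path, row.names = FALSE)
  invisible(path)
}

#' Read a life table from CSV
#'
#' @param path CSV with columns `age`, `qx`.
#' @return data frame with columns `age`, `qx`.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(lt)))
    stop("life-table CSV must have columns age, qx")
  lt[c("age", "qx")]
}

wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Simulate two-arm trial outcomes
#'
#' Emulates the statistical structure of a two-arm trial in which each
#' randomized patient ends the acute episode cured, dead, or neither: a
#' multinomial draw per arm. Returns counts, point estimates, and Wilson 95%
#' binomial confidence intervals, ready to feed into a parameter set as
#' cure/mortality rates with bounds.
#'
#' @param true_cure,true_mort true per-arm probabilities; scalars are recycled
#'   to both arms, or give length-2 vectors named/ordered as
#'   (`ctz_taz`, `mepm`).
#' @param n_per_arm patients randomized per arm.
#' @param seed integer seed (the draw is reproducible given the seed).
#' @return object of class `"synthetic_trial"`: a data frame with one row per
#'   arm and columns `arm`, `n`, `n_cured`, `n_died`, `cure`, `cure_lower`,
#'   `cure_upper`, `mort`, `mort_lower`, `mort_upper`.
#' @examples
#' simulate_trial(c(0.606, 0.571), c(0.201, 0.255), n_per_arm = 360, seed = 1)
#' @export
simulate_trial <- function(true_cure, true_mort, n_per_arm, seed) {
  true_cure <- rep_len(as.numeric(true_cure), 2L)
  true_mort <- rep_len(as.numeric(true_mort), 2L)
  if (any(true_cure < 0 | true_cure > 1 | true_mort < 0 | true_mort > 1) ||
      any(true_cure + true_mort > 1))
    stop("infeasible true rates: need cure, mort in [0,1] and cure + mort <= 1")
  stopifnot(n_per_arm >= 1)
  set.seed(as.integer(seed))
  arms <- c("ctz_taz", "mepm")
  rows <- lapply(seq_along(arms), function(i) {
    counts <- stats::rmultinom(1L, n_per_arm,
                               c(true_cure[i], true_mort[i],
                                 1 - true_cure[i] - true_mort[i]))[, 1L]
    ci_c <- wilson_ci(counts[1L], n_per_arm)
    ci_m <- wilson_ci(counts[2L], n_per_arm)
    data.frame(arm = arms[i], n = n_per_arm,
               n_cured = counts[1L], n_died = counts[2L],
               cure = counts[1L] / n_per_arm,
               cure_lower = ci_c[["lower"]], cure_upper = ci_c[["upper"]],
               mort = counts[2L] / n_per_arm,
               mort_lower = ci_m[["lower"]], mort_upper = ci_m[["upper"]])
  })
  structure(do.call(rbind, rows), class = c("synthetic_trial", "data.frame"))
}

#' Build a parameter set from simulated trial outcomes
#'
#' Replaces the first-line cure/mortality point estimates and bounds of a base
#' parameter set with the estimates from a [simulate_trial()] result, then
#' rederives the second-line rates by the stated derivation rule (cure reduced
#' by the configured fraction, mortality increased by the configured
#' fraction).
#'
#' @param trial a `synthetic_trial` object.
#' @param base parameter set to update (defaults to [reference_inputs()]).
#' @return a validated `cea_parameters` object.
#' @export
parameters_from_trial <- function(trial, base = reference_inputs()) {
  for (i in seq_len(nrow(trial))) {
    a <- trial$arm[i]
    base$arms[[a]]$efficacy$cure_first <-
      rwb(trial$cure[i], trial$cure_lower[i], trial$cure_upper[i])
    base$arms[[a]]$efficacy$mort_first <-
      rwb(trial$mort[i], trial$mort_lower[i], trial$mort_upper[i])
    d2 <- derive_second_line(
      trial$cure[i], trial$mort[i],
      base$settings$second_line_cure_reduction,
      base$settings$second_line_mort_increase)
    base$arms[[a]]$efficacy$cure_second <-
      rwb(d2[["cure"]],
          trial$cure_lower[i] * (1 - base$settings$second_line_cure_reduction),
          trial$cure_upper[i] * (1 - base$settings$second_line_cure_reduction))
    base$arms[[a]]$efficacy$mort_second <-
      rwb(d2[["mort"]],
          min(1, trial$mort_lower[i] * (1 + base$settings$second_line_mort_increase)),
          min(1, trial$mort_upper[i] * (1 + base$settings$second_line_mort_increase)))
  }
  validate_parameters(base, warn = FALSE)
}

#' Write a trial summary to CSV
#'
#' @param trial a `synthetic_trial` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_summary <- function(trial, path) {
  utils::write.csv(as.data.frame(trial), path, row.names = FALSE)
  invisible(path)
}
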