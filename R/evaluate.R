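#' Incremental cost-effectiveness ratio
#'
#' `delta_cost / delta_qaly` when both increments are positive;
#' `"dominant"` when the intervention is cheaper and more effective;
#' `"dominated"` when costlier and less effective; `"undefined"` when the
#' QALY increment is zero. When both increments are negative the ratio is
#' still returned (a southwest-quadrant trade-off).
#'
#' @param delta_cost incremental cost (yen), intervention minus comparator.
#' @param delta_qaly incremental QALYs.
#' @return list with `value` (yen/QALY or `NA`) and `label` (`"ratio"`,
#'   `"dominant"`, `"dominated"`, `"undefined"`).
#' @examples
#' icer(100, 0.5)   # 200/QALY
#' icer(-1, 0.1)    # dominant
#' @export
icer <- function(delta_cost, delta_qaly) {
  if (delta_qaly == 0)
    return(list(value = NA_real_, label = "undefined"))
  if (delta_qaly > 0 && delta_cost < 0)
    return(list(value = NA_real_, label = "dominant"))
  if (delta_qaly < 0 && delta_cost > 0)
    return(list(value = NA_real_, label = "dominated"))
  list(value = delta_cost / delta_qaly, label = "ratio")
}

#' Incremental net monetary benefit
#'
#' `wtp * delta_qaly - delta_cost`. Positive exactly when the ICER is below
#' the willingness-to-pay threshold (for a positive QALY increment).
#'
#' @param delta_cost incremental cost (yen).
#' @param delta_qaly incremental QALYs.
#' @param wtp willingness-to-pay threshold (yen/QALY, >= 0).
#' @return yen.
#' @examples
#' inmb(424731.22, 0.17, 5e6)
#' @export
inmb <- function(delta_cost, delta_qaly, wtp) {
  stopifnot(wtp >= 0)
  wtp * delta_qaly - delta_cost
}

#' Evaluate one arm end to end
#'
#' Acute decision tree plus long-term cohort propagation; acute costs and
#' QALYs are undiscounted (they fall in the first model year), long-term
#' increments are discounted from model entry.
#'
#' @param arm `"ctz_taz"` or `"mepm"`.
#' @param params a `cea_parameters` object.
#' @return list with `acute` (an `acute_outcome`), `markov`, `total_cost`,
#'   `total_qaly`.
#' @export
evaluate_arm <- function(arm, params) {
  ao <- evaluate_acute(arm, params)
  mk <- run_cohort_from_tree(ao$end_states, markov_spec(params))
  list(arm = arm, acute = ao, markov = mk,
       total_cost = ao$expected_cost + mk$total_cost,
       total_qaly = ao$acute_qaly + mk$total_qaly)
}

#' Evaluate the full cost-effectiveness comparison
#'
#' The package's main entry point: evaluates both arms through the acute
#' decision tree and the long-term Markov cohort model, and reports total
#' discounted costs and QALYs, their increments, the ICER (from unrounded
#' increments), and (incremental) net monetary benefit at the
#' willingness-to-pay threshold.
#'
#' @param params a `cea_parameters` object, e.g. [reference_inputs()].
#' @param wtp willingness-to-pay threshold (yen/QALY); defaults to the one in
#'   `params$settings`.
#' @param intervention,comparator arm ids; increments are intervention minus
#'   comparator.
#' @return object of class `"cea_result"` with per-arm results (`arms`),
#'   `delta_cost`, `delta_qaly`, `icer`, `icer_label`, `nmb` (per arm),
#'   `inmb`, `wtp`.
#' @examples
#' res <- evaluate_ce(reference_inputs())
#' res
#' @export
evaluate_ce <- function(params, wtp = params$settings$wtp,
                        intervention = "ctz_taz", comparator = "mepm") {
  arms <- list()
  for (arm in c(comparator, intervention))
    arms[[arm]] <- evaluate_arm(arm, params)
  dc <- arms[[intervention]]$total_cost - arms[[comparator]]$total_cost
  dq <- arms[[intervention]]$total_qaly - arms[[comparator]]$total_qaly
  ic <- icer(dc, dq)
  nmb <- vapply(arms, function(a) wtp * a$total_qaly - a$total_cost,
                numeric(1))
  structure(list(
    arms = arms, intervention = intervention, comparator = comparator,
    delta_cost = dc, delta_qaly = dq,
    icer = ic$value, icer_label = ic$label,
    nmb = nmb, inmb = inmb(dc, dq, wtp), wtp = wtp
  ), class = "cea_result")
}

fmt_yen <- function(x) formatC(x, format = "f", digits = 2, big.mark = ",")

#' @export
print.cea_result <- function(x, ...) {
  cat("Cost-effectiveness results (", x$intervention, " vs ",
      x$comparator, ")\n", sep = "")
  for (arm in names(x$arms)) {
    a <- x$arms[[arm]]
    cat(sprintf("  %-8s total cost %15s yen   total QALYs %6.2f\n",
                arm, fmt_yen(a$total_cost), a$total_qaly))
  }
  cat(sprintf("  incremental cost  %15s yen\n", fmt_yen(x$delta_cost)))
  cat(sprintf("  incremental QALYs %15.4f\n", x$delta_qaly))
  if (x$icer_label == "ratio")
    cat(sprintf("  ICER              %15s yen/QALY\n", fmt_yen(x$icer)))
  else cat("  ICER              ", x$icer_label, "\n")
  cat(sprintf("  INMB at WTP %s: %s yen\n",
              format(x$wtp, big.mark = ",", scientific = FALSE),
              fmt_yen(x$inmb)))
  invisible(x)
}

#' @export
summary.cea_result <- function(object, ...) {
  x <- object
  df <- data.frame(
    arm = names(x$arms),
    total_cost = vapply(x$arms, function(a) a$total_cost, numeric(1)),
    total_qaly = vapply(x$arms, function(a) a$total_qaly, numeric(1)),
    acute_cost = vapply(x$arms, function(a) a$acute$expected_cost, numeric(1)),
    acute_qaly = vapply(x$arms, function(a) a$acute$acute_qaly, numeric(1)),
    markov_qaly = vapply(x$arms, function(a) a$markov$total_qaly, numeric(1)),
    nmb = unname(x$nmb),
    row.names = NULL
  )
  structure(list(arms = df, delta_cost = x$delta_cost,
                 delta_qaly = x$delta_qaly, icer = x$icer,
                 icer_label = x$icer_label, inmb = x$inmb, wtp = x$wtp),
            class = "summary.cea_result")
}

#' @export
print.summary.cea_result <- function(x, ...) {
  print(x$arms, row.names = FALSE)
  cat(sprintf("delta cost %s yen, delta QALYs %.4f, ICER %s, INMB %s yen\n",
              fmt_yen(x$delta_cost), x$delta_qaly,
              if (x$icer_label == "ratio") fmt_yen(x$icer) else x$icer_label,
              fmt_yen(x$inmb)))
  invisible(x)
}

#' Result record as a flat list (for JSON/CSV export)
#'
#' @param x a `cea_result`.
#' @return named list mirroring the base-case summary table.
#' @export
as_record <- function(x) {
  stopifnot(inherits(x, "cea_result"))
  list(
    intervention = x$intervention, comparator = x$comparator,
    cost_intervention = x$arms[[x$intervention]]$total_cost,
    cost_comparator = x$arms[[x$comparator]]$total_cost,
    qaly_intervention = x$arms[[x$intervention]]$total_qaly,
    qaly_comparator = x$arms[[x$comparator]]$total_qaly,
    delta_cost = x$delta_cost, delta_qaly = x$delta_qaly,
    icer = x$icer, icer_label = x$icer_label,
    wtp = x$wtp, inmb = x$inmb
  )
}
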