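# Setting an efficacy rate to a bound can make cure + mortality exceed 1 for
# its treatment line; the swept value is then truncated to feasibility and
# flagged rather than silently evaluated.
efficacy_partner <- function(id) {
  if (!grepl("\\.efficacy\\.", id)) return(NULL)
  leaf <- sub("^.*\\.", "", id)
  partner_leaf <- switch(leaf,
    cure_first = "mort_first", mort_first = "cure_first",
    cure_second = "mort_second", mort_second = "cure_second", NULL)
  if (is.null(partner_leaf)) return(NULL)
  sub("\\.[^.]+$", paste0(".", partner_leaf), id)
}

set_feasible <- function(params, id, value) {
  truncated <- FALSE
  partner <- efficacy_partner(id)
  if (!is.null(partner)) {
    other <- pt_est(param_get(params, partner))
    if (value + other > 1) { value <- 1 - other; truncated <- TRUE }
    if (value < 0) { value <- 0; truncated <- TRUE }
  }
  list(params = param_set(params, id, value), value = value,
       truncated = truncated)
}

#' One-way sensitivity analysis (tornado)
#'
#' Re-evaluates the full model with each bounded parameter set to its lower
#' and upper bound in turn (all other parameters at base values) and reports
#' the incremental net monetary benefit at the willingness-to-pay threshold.
#' Entries are ordered by descending INMB range; a parameter whose swept INMB
#' interval straddles zero is flagged (`crosses_zero`): the cost-effectiveness
#' conclusion flips inside its plausible range.
#'
#' Efficacy rates are swept jointly with their complements: the residual
#' branch (second-line entry, or long-term ICU) renormalizes through the
#' tree; a bound that would make `cure + mortality > 1` is truncated to the
#' feasible boundary and flagged in `truncated`.
#'
#' @param params a `cea_parameters` object.
#' @param wtp willingness-to-pay (yen/QALY).
#' @param ids parameter paths to sweep; default: every parameter with finite
#'   bounds.
#' @return object of class `"cea_owsa"`: a data frame with one row per
#'   parameter (`parameter`, `base_value`, `lower`, `upper`, `inmb_lower`,
#'   `inmb_upper`, `range`, `crosses_zero`, `truncated`), sorted by
#'   descending `range`, with the base-case INMB in attribute `"base_inmb"`.
#' @examples
#' \donttest{
#' tor <- run_owsa(reference_inputs())
#' head(tor)
#' }
#' @export
run_owsa <- function(params, wtp = params$settings$wtp, ids = NULL) {
  if (is.null(ids)) ids <- bounded_parameter_ids(params)
  base <- evaluate_ce(params, wtp = wtp)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[[i]]
    leaf <- param_get(params, id)
    # explicitly requested degenerate bounds still evaluate (range 0);
    # parameters without bounds are skipped
    if (!inherits(leaf, "rwb") ||
        !(is.finite(leaf[["lower"]]) && is.finite(leaf[["upper"]]))) next
    vals <- c(leaf[["lower"]], leaf[["upper"]])
    inmbs <- numeric(2); trunc <- FALSE
    for (j in 1:2) {
      sf <- set_feasible(params, id, vals[j])
      trunc <- trunc || sf$truncated
      inmbs[j] <- evaluate_ce(sf$params, wtp = wtp)$inmb
    }
    rows[[i]] <- data.frame(
      parameter = id, base_value = unname(leaf[["value"]]),
      lower = vals[1], upper = vals[2],
      inmb_lower = inmbs[1], inmb_upper = inmbs[2],
      range = abs(inmbs[2] - inmbs[1]),
      crosses_zero = min(inmbs) < 0 && max(inmbs) > 0,
      truncated = trunc, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- out[order(-out$range), ]
  rownames(out) <- NULL
  # base case must be bit-identical after the sweep (no state leakage)
  base_after <- evaluate_ce(params, wtp = wtp)
  if (!identical(base$inmb, base_after$inmb))
    stop("internal error: base case changed during the sweep")
  structure(out, class = c("cea_owsa", "data.frame"),
            base_inmb = base$inmb, wtp = wtp)
}

#' @export
print.cea_owsa <- function(x, n = 15L, ...) {
  cat("One-way sensitivity analysis: INMB at WTP",
      format(attr(x, "wtp"), big.mark = ","), "yen/QALY\n")
  cat("base-case INMB:", fmt_yen(attr(x, "base_inmb")), "yen\n")
  print(utils::head(as.data.frame(x), n), row.names = FALSE)
  if (nrow(x) > n) cat("...", nrow(x) - n, "more parameters\n")
  invisible(x)
}

#' Tornado plot
#'
#' Horizontal bars from the lower-bound INMB to the upper-bound INMB for the
#' `n` widest-ranging parameters, with the base-case INMB and zero marked.
#'
#' @param x a `cea_owsa` object.
#' @param n how many parameters to draw (widest first).
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.cea_owsa <- function(x, n = 15L, ...) {
  d <- utils::head(as.data.frame(x), n)
  d <- d[rev(seq_len(nrow(d))), ]
  base <- attr(x, "base_inmb")
  xlim <- range(c(d$inmb_lower, d$inmb_upper, base, 0))
  old <- graphics::par(mar = c(4.5, 14, 2.5, 1)); on.exit(graphics::par(old))
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, nrow(d) + 0.5),
                 yaxt = "n", xlab = "INMB (yen)", ylab = "",
                 main = "One-way sensitivity analysis")
  for (i in seq_len(nrow(d))) {
    lo <- min(d$inmb_lower[i], d$inmb_upper[i])
    hi <- max(d$inmb_lower[i], d$inmb_upper[i])
    graphics::rect(lo, i - 0.35, hi, i + 0.35, col = "steelblue",
                   border = "grey30")
  }
  graphics::abline(v = base, lty = 2)
  graphics::abline(v = 0, col = "red3")
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$parameter, las = 1,
                 cex.axis = 0.7)
  invisible(x)
}
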