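#' Distribution specifications for the probabilistic sensitivity analysis
#'
#' Assigns each bounded parameter a sampling distribution by health-economics
#' convention: beta for probabilities and the two non-negative utilities,
#' normal for the ventilated-ICU utility (it may be negative), gamma for
#' costs and durations. Scale parameters are moment-matched to the point
#' estimate and `SE = (upper - lower) / (2 * 1.96)` (bounds read as a 95%
#' interval). A beta whose variance exceeds `m(1-m)` is unmatchable and falls
#' back to uniform(lower, upper) with a warning. Parameters without bounds
#' are held fixed, as is the discount rate (varied only in the one-way
#' analysis).
#'
#' @param params a `cea_parameters` object.
#' @param force_family optional family name applied to every sampled
#'   parameter (used for distribution-shape diagnostics).
#' @return data frame `id`, `family`, `mean`, `se`, `lower`, `upper`,
#'   `par1`, `par2` (shape1/shape2 for beta, shape/rate for gamma, mean/sd
#'   for normal, lower/upper for uniform).
#' @export
psa_spec_table <- function(params, force_family = NULL) {
  ids <- bounded_parameter_ids(params,
                               exclude = "settings.discount_rate_annual")
  if (!length(ids))
    return(data.frame(id = character(), family = character(),
                      mean = numeric(), se = numeric(), lower = numeric(),
                      upper = numeric(), par1 = numeric(), par2 = numeric(),
                      stringsAsFactors = FALSE))
  rows <- lapply(ids, function(id) {
    x <- param_get(params, id)
    m <- x[["value"]]; lo <- x[["lower"]]; up <- x[["upper"]]
    se <- (up - lo) / (2 * stats::qnorm(0.975))
    family <- if (!is.null(force_family)) force_family
    else if (id == "utilities.u_icu_vent") "normal"
    else if (is_rate_path(id) || grepl("^utilities\\.", id)) "beta"
    else "gamma"
    par1 <- par2 <- NA_real_
    if (family == "beta") {
      v <- se^2
      if (m <= 0 || m >= 1 || v >= m * (1 - m)) {
        warning("beta moments unmatchable for ", id,
                "; falling back to uniform(lower, upper)", call. = FALSE)
        family <- "uniform"; par1 <- lo; par2 <- up
      } else {
        nu <- m * (1 - m) / v - 1
        par1 <- m * nu; par2 <- (1 - m) * nu
      }
    }
    if (family == "gamma") {
      if (m <= 0 || se <= 0) {
        family <- "fixed"
      } else {
        par1 <- m^2 / se^2; par2 <- m / se^2   # shape, rate
      }
    }
    if (family == "normal") { par1 <- m; par2 <- se }
    if (family == "uniform" && is.na(par1)) { par1 <- lo; par2 <- up }
    data.frame(id = id, family = family, mean = m, se = se,
               lower = lo, upper = up, par1 = par1, par2 = par2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Draw parameter samples for the PSA
#'
#' One seeded generator; parameters are sampled in a canonical order (their
#' sorted dotted paths, the row order of [psa_spec_table()]), `n` draws per
#' parameter, so results are reproducible across runs and platforms for a
#' given seed. Draws from a `fixed` family equal the point estimate. The
#' normally distributed ICU utility is clamped to \[-1, 1\].
#'
#' @param params a `cea_parameters` object.
#' @param n number of draws.
#' @param seed integer seed.
#' @param spec optional precomputed [psa_spec_table()].
#' @return numeric matrix `n x n_parameters`, column names = parameter paths.
#' @export
sample_parameters <- function(params, n, seed, spec = NULL) {
  if (is.null(spec)) spec <- psa_spec_table(params)
  set.seed(as.integer(seed))
  draws <- matrix(NA_real_, nrow = n, ncol = nrow(spec),
                  dimnames = list(NULL, spec$id))
  for (j in seq_len(nrow(spec))) {
    s <- spec[j, ]
    x <- switch(s$family,
      beta    = stats::rbeta(n, s$par1, s$par2),
      gamma   = stats::rgamma(n, shape = s$par1, rate = s$par2),
      normal  = stats::rnorm(n, s$par1, s$par2),
      uniform = stats::runif(n, s$par1, s$par2),
      fixed   = rep(s$mean, n),
      stop("unknown family: ", s$family))
    # the ICU utility is the one conventionally-normal parameter with a
    # bounded domain; keep its draws inside it
    if (s$id == "utilities.u_icu_vent") x <- pmin(1, pmax(-1, x))
    draws[, j] <- x
  }
  draws
}

apply_draw <- function(params, draw) {
  for (id in names(draw)) {
    v <- draw[[id]]
    # guard domains (relevant only for injected non-conventional specs):
    # rates and the two positive utilities live in [0,1], the ICU utility in
    # [-1,1], costs and durations are non-negative
    if (is_rate_path(id) ||
        id %in% c("utilities.u_discharged", "utilities.u_ward"))
      v <- min(1, max(0, v))
    else if (id == "utilities.u_icu_vent") v <- min(1, max(-1, v))
    else v <- max(0, v)
    sf <- set_feasible(params, id, v)
    params <- sf$params
  }
  params
}

#' Probabilistic sensitivity analysis
#'
#' Samples every uncertain parameter from its assigned distribution
#' ([psa_spec_table()]), evaluates the full model per draw, and summarizes:
#' the cost-effectiveness plane (per-draw incremental cost and QALYs), the
#' probability each strategy is optimal (highest net monetary benefit, ties
#' split equally) at the base willingness-to-pay, and the acceptability curve
#' over a WTP grid.
#'
#' @param params a `cea_parameters` object.
#' @param n_iter number of Monte-Carlo draws (>= 1).
#' @param seed integer seed; the same seed and inputs reproduce every draw
#'   and curve exactly.
#' @param wtp base willingness-to-pay (yen/QALY).
#' @param wtp_grid thresholds for the acceptability curve (yen/QALY).
#' @param spec optional [psa_spec_table()] override (e.g. with
#'   `force_family`); defaults to the conventional families.
#' @return object of class `"cea_psa"`: `draws` (data frame `draw`,
#'   `delta_cost`, `delta_qaly`, per-draw `inmb`), `p_optimal` (named,
#'   intervention/comparator, at `wtp`), `ceac` (data frame `wtp`,
#'   `p_intervention`, `p_comparator`), plus the spec table and seed.
#' @examples
#' \donttest{
#' psa <- run_psa(reference_inputs(), n_iter = 100, seed = 1)
#' psa$p_optimal
#' }
#' @export
run_psa <- function(params, n_iter = 1000, seed = 1,
                    wtp = params$settings$wtp,
                    wtp_grid = seq(0, 2e7, by = 5e5), spec = NULL) {
  stopifnot(n_iter >= 1)
  if (is.null(spec)) spec <- psa_spec_table(params)
  draws <- sample_parameters(params, n_iter, seed, spec = spec)
  dc <- dq <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    p_i <- apply_draw(params, draws[i, ])
    r <- evaluate_ce(p_i, wtp = wtp)
    dc[i] <- r$delta_cost; dq[i] <- r$delta_qaly
  }
  p_opt_at <- function(lambda) {
    b <- lambda * dq - dc
    mean((b > 0) + 0.5 * (b == 0))
  }
  p_int <- p_opt_at(wtp)
  ceac <- data.frame(wtp = wtp_grid,
                     p_intervention = vapply(wtp_grid, p_opt_at, numeric(1)))
  ceac$p_comparator <- 1 - ceac$p_intervention
  structure(list(
    draws = data.frame(draw = seq_len(n_iter), delta_cost = dc,
                       delta_qaly = dq, inmb = wtp * dq - dc),
    p_optimal = c(intervention = p_int, comparator = 1 - p_int),
    ceac = ceac, wtp = wtp, seed = seed, n_iter = n_iter, spec = spec
  ), class = "cea_psa")
}

#' @export
print.cea_psa <- function(x, ...) {
  cat("Probabilistic sensitivity analysis:", x$n_iter, "draws (seed",
      x$seed, ")\n")
  cat(sprintf("  mean delta cost  %s yen\n", fmt_yen(mean(x$draws$delta_cost))))
  cat(sprintf("  mean delta QALYs %.4f\n", mean(x$draws$delta_qaly)))
  cat(sprintf("  P(intervention optimal at WTP %s): %.1f%%\n",
              format(x$wtp, big.mark = ",", scientific = FALSE),
              100 * x$p_optimal[["intervention"]]))
  invisible(x)
}

#' Plot PSA results
#'
#' `type = "plane"`: incremental cost vs incremental QALYs per draw with the
#' WTP threshold line through the origin. `type = "ceac"`: probability each
#' strategy is optimal against the WTP threshold.
#'
#' @param x a `cea_psa` object.
#' @param type `"plane"` or `"ceac"`.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.cea_psa <- function(x, type = c("plane", "ceac"), ...) {
  type <- match.arg(type)
  if (type == "plane") {
    graphics::plot(x$draws$delta_qaly, x$draws$delta_cost, pch = 16,
                   col = grDevices::adjustcolor("steelblue", 0.5),
                   xlab = "Incremental QALYs", ylab = "Incremental cost (yen)",
                   main = "Cost-effectiveness plane")
    graphics::abline(h = 0, v = 0, col = "grey60")
    graphics::abline(a = 0, b = x$wtp, lty = 2, col = "red3")
  } else {
    graphics::plot(x$ceac$wtp, x$ceac$p_intervention, type = "l", lwd = 2,
                   col = "steelblue", ylim = c(0, 1),
                   xlab = "Willingness-to-pay (yen/QALY)",
                   ylab = "Probability cost-effective",
                   main = "Cost-effectiveness acceptability curve")
    graphics::lines(x$ceac$wtp, x$ceac$p_comparator, lwd = 2, col = "grey40")
    graphics::abline(v = x$wtp, lty = 2)
    graphics::legend("right", legend = c("intervention", "comparator"),
                     col = c("steelblue", "grey40"), lwd = 2, bty = "n")
  }
  invisible(x)
}

#' Write the CE-plane scatter to CSV
#'
#' @param psa a `cea_psa` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ce_plane <- function(psa, path) {
  utils::write.csv(psa$draws, path, row.names = FALSE)
  invisible(path)
}

#' Write the acceptability curve to CSV
#'
#' @param psa a `cea_psa` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ceac <- function(psa, path) {
  utils::write.csv(psa$ceac, path, row.names = FALSE)
  invisible(path)
}
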