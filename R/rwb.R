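#' Quantity with uncertainty bounds
#'
#' Most model inputs carry a point estimate plus a (lower, upper) pair read as
#' a 95% interval: efficacy rates, durations, adverse-event costs, utilities.
#' `rwb()` bundles the three numbers; bounds may be absent (`NA`), in which
#' case the parameter is held fixed in sensitivity analyses.
#'
#' A point estimate lying outside its own printed interval is possible in the
#' source tables (typographic bound anomalies); it is therefore *warned about*
#' at validation time, never rejected.
#'
#' @param value point estimate.
#' @param lower,upper optional interval bounds, `lower <= upper`.
#' @return an object of class `"rwb"` (a named numeric triple).
#' @examples
#' rwb(0.571, 0.49, 0.75)
#' pt_est(rwb(0.8))
#' @export
rwb <- function(value, lower = NA_real_, upper = NA_real_) {
  stopifnot(is.numeric(value), length(value) == 1L)
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != 1L || length(upper) != 1L)
    stop("lower/upper must be scalars")
  if (is.finite(lower) && is.finite(upper) && lower > upper)
    stop("rwb: lower (", lower, ") > upper (", upper, ")")
  structure(c(value = as.numeric(value), lower = lower, upper = upper),
            class = "rwb")
}

#' Point estimate of a bounded quantity
#'
#' @param x an `rwb` object or plain numeric scalar.
#' @return the point estimate as a bare numeric.
#' @export
pt_est <- function(x) {
  if (inherits(x, "rwb")) unname(x[["value"]]) else as.numeric(x)
}

#' @export
print.rwb <- function(x, ...) {
  b <- if (is.finite(x[["lower"]]) || is.finite(x[["upper"]]))
    sprintf(" [%s, %s]", format(x[["lower"]]), format(x[["upper"]])) else ""
  cat(format(x[["value"]]), b, "\n", sep = "")
  invisible(x)
}

has_bounds <- function(x) {
  inherits(x, "rwb") && is.finite(x[["lower"]]) && is.finite(x[["upper"]]) &&
    x[["upper"]] > x[["lower"]]
}

# ---- dotted-path access into the nested parameter list ----------------------

split_path <- function(id) strsplit(id, ".", fixed = TRUE)[[1L]]

#' Read a parameter by dotted path
#'
#' Parameters live in a nested list; sensitivity analyses address them by a
#' dotted path such as `"arms.mepm.efficacy.cure_first"`.
#'
#' @param params a [cea_parameters] object (or plain nested list).
#' @param id dotted path string.
#' @return the element at that path (often an `rwb`).
#' @export
param_get <- function(params, id) {
  node <- params
  for (k in split_path(id)) {
    if (is.null(node[[k]])) stop("unknown parameter path: ", id)
    node <- node[[k]]
  }
  node
}

#' Replace a parameter's point estimate by dotted path
#'
#' Keeps the stored bounds; only the point estimate is replaced. Used by the
#' one-way and probabilistic sensitivity analyses so a swept copy never
#' mutates the caller's object.
#'
#' @param params a [cea_parameters] object.
#' @param id dotted path string.
#' @param value new point estimate.
#' @return the modified parameter object.
#' @export
param_set <- function(params, id, value) {
  keys <- split_path(id)
  rec <- function(node, keys) {
    k <- keys[[1L]]
    if (is.null(node[[k]])) stop("unknown parameter path: ", id)
    if (length(keys) == 1L) {
      node[[k]] <- if (inherits(node[[k]], "rwb"))
        rwb(value, node[[k]][["lower"]], node[[k]][["upper"]])
      else as.numeric(value)
    } else {
      node[[k]] <- rec(node[[k]], keys[-1L])
    }
    node
  }
  out <- rec(unclass(params), keys)
  class(out) <- class(params)
  out
}

# Walk the nested list and return dotted paths of every rwb leaf that carries
# finite, non-degenerate bounds (these are the sweepable/samplable parameters).
bounded_parameter_ids <- function(params, exclude = character()) {
  out <- character()
  rec <- function(node, prefix) {
    if (inherits(node, "rwb")) {
      if (has_bounds(node)) out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    if (is.list(node)) {
      for (k in names(node)) {
        rec(node[[k]], if (nzchar(prefix)) paste(prefix, k, sep = ".") else k)
      }
    }
  }
  rec(unclass(params), "")
  sort(setdiff(out, exclude))
}
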