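#' Specify a causal dose-response curve on the log-odds scale
#'
#' Defines the shape of the true causal effect of sleep duration (hours) on
#' the log-odds of a binary metabolic outcome, used by [simulate_cohort()]
#' to generate outcomes and by [true_lace()] as the oracle for stratified
#' estimates. All shapes are parameterized as a continuous piecewise-linear
#' function with a single breakpoint: a slope below the breakpoint and a
#' slope above it, anchored at zero at the breakpoint.
#'
#' @param shape one of `"linear"`, `"l_shaped"`, `"u_shaped"`, `"null"`.
#' @param slope log-odds change per hour for `shape = "linear"`, or the
#'   magnitude of both arms for `"u_shaped"`.
#' @param slope_below,slope_above arm slopes (log-odds per hour) for
#'   `"l_shaped"`; ignored for other shapes.
#' @param breakpoint hour at which the two arms meet; must lie in `[4, 11]`.
#'
#' @return An object of class `dose_response`: a list with elements
#'   `shape`, `breakpoint`, `slope_below`, `slope_above`.
#'
#' @details Shape conventions:
#' * `linear`: the same slope on both sides of the breakpoint.
#' * `l_shaped`: a non-zero slope below the breakpoint (default `-0.3`,
#'   i.e. risk falls as short sleepers approach the breakpoint) and a flat
#'   arm above it.
#' * `u_shaped`: slopes `-slope` below and `+slope` above the breakpoint
#'   (default breakpoint 7.5 h), so risk rises away from the nadir.
#' * `null`: flat everywhere.
#'
#' @examples
#' dr <- dose_response("l_shaped", slope_below = -0.3, breakpoint = 7)
#' dr_value(dr, 4:11)
#' @export
dose_response <- function(shape = c("linear", "l_shaped", "u_shaped", "null"),
                          slope = -0.14,
                          slope_below = -0.3,
                          slope_above = 0,
                          breakpoint = NULL) {
  shape <- match.arg(shape)
  breakpoint <- breakpoint %||% switch(shape, u_shaped = 7.5, 7)
  if (!is.numeric(breakpoint) || length(breakpoint) != 1L ||
      breakpoint < 4 || breakpoint > 11) {
    abort("`breakpoint` must be a single number in [4, 11].")
  }
  arms <- switch(shape,
    linear   = c(slope, slope),
    l_shaped = c(slope_below, slope_above),
    u_shaped = c(-abs(slope), abs(slope)),
    null     = c(0, 0)
  )
  structure(
    list(shape = shape, breakpoint = breakpoint,
         slope_below = arms[[1]], slope_above = arms[[2]]),
    class = "dose_response"
  )
}

#' Evaluate a dose-response curve
#'
#' Returns the log-odds contribution of sleep duration `hours` relative to
#' the curve's breakpoint (where the curve is anchored at zero).
#'
#' @param dr a [dose_response()] object.
#' @param hours numeric vector of sleep durations in hours.
#' @return numeric vector of log-odds values, same length as `hours`.
#' @export
dr_value <- function(dr, hours) {
  stopifnot(inherits(dr, "dose_response"))
  bp <- dr$breakpoint
  dr$slope_below * (pmin(hours, bp) - bp) +
    dr$slope_above * (pmax(hours, bp) - bp)
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf(
    "<dose_response: %s> breakpoint %.2g h, slopes (%.3g, %.3g) log-odds/h\n",
    x$shape, x$breakpoint, x$slope_below, x$slope_above))
  invisible(x)
}

#' True localized average causal effects from simulation ground truth
#'
#' Computes the average gradient of the generating dose-response curve over
#' each interval delimited by `boundaries`, in log-odds per hour. This is
#' the oracle against which stratum-level LACE estimates from
#' [lace_per_stratum()] can be compared.
#'
#' @param truth a `sleepmr_truth` object from [simulate_cohort()], or a
#'   [dose_response()] object directly.
#' @param boundaries increasing numeric vector of hour values within
#'   `[4, 11]`; `length(boundaries) - 1` intervals are evaluated.
#' @return numeric vector of average slopes, one per interval.
#' @examples
#' dr <- dose_response("l_shaped", slope_below = -0.3, breakpoint = 7)
#' true_lace(dr, c(4, 7, 11))
#' @export
true_lace <- function(truth, boundaries) {
  dr <- if (inherits(truth, "sleepmr_truth")) truth$dose_response else truth
  stopifnot(inherits(dr, "dose_response"))
  if (length(boundaries) < 2L || is.unsorted(boundaries, strictly = TRUE)) {
    abort("`boundaries` must be strictly increasing with length >= 2.")
  }
  if (min(boundaries) < 4 || max(boundaries) > 11) {
    abort("`boundaries` must lie within [4, 11].")
  }
  g <- dr_value(dr, boundaries)
  diff(g) / diff(boundaries)
}
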