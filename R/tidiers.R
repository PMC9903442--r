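#' Tidy an MR estimate
#'
#' One row per model term: the causal slope always, plus the intercept
#' row for MR-Egger fits.
#'
#' @param x an `mr_fit`.
#' @param exponentiate return odds ratios instead of log odds ratios?
#' @param ... unused.
#' @return Tibble: `method`, `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `p.value`, `scale`.
#' @method tidy mr_fit
#' @export
tidy.mr_fit <- function(x, exponentiate = FALSE, ...) {
  out <- tibble(
    method = x$method, term = "causal_effect",
    estimate = x$beta, std.error = x$se,
    conf.low = x$ci_lo, conf.high = x$ci_hi,
    p.value = x$p, scale = x$scale
  )
  if (!is.null(x$egger_intercept)) {
    out <- dplyr::bind_rows(out, tibble(
      method = x$method, term = "intercept",
      estimate = x$egger_intercept, std.error = x$intercept_se,
      conf.low = x$egger_intercept - 1.96 * (x$intercept_se %||% NA_real_),
      conf.high = x$egger_intercept + 1.96 * (x$intercept_se %||% NA_real_),
      p.value = x$intercept_p, scale = x$scale
    ))
  }
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' Model-level summary of an MR estimate
#'
#' @param x an `mr_fit`.
#' @param ... unused.
#' @return One-row tibble with method, OR and CI, heterogeneity Q (when
#'   available), number of SNPs and observations.
#' @method glance mr_fit
#' @export
glance.mr_fit <- function(x, ...) {
  tibble(
    method = x$method, or = exp(x$beta),
    or_low = exp(x$ci_lo), or_high = exp(x$ci_hi),
    p.value = x$p, scale = x$scale,
    q = x$q %||% NA_real_, q_p = x$q_p %||% NA_real_,
    n_snps = x$n_snps, nobs = x$nobs
  )
}

#' @method tidy mr_radial
#' @export
tidy.mr_radial <- function(x, ...) x$snps

#' @method glance mr_radial
#' @export
glance.mr_radial <- function(x, ...) {
  tibble(
    beta = x$beta, se = x$se, global_q = x$global_q, q_df = x$q_df,
    q_p = x$q_p, n_outliers = sum(x$snps$outlier), alpha = x$alpha,
    iterations = x$iterations
  )
}

#' @method tidy mr_nonlinear
#' @export
tidy.mr_nonlinear <- function(x, ...) x$strata

#' @method glance mr_nonlinear
#' @export
glance.mr_nonlinear <- function(x, ...) {
  tibble(
    outcome = x$outcome, k = x$k, shape = x$shape,
    quadratic_p = x$quadratic$p,
    cochran_q = x$cochran$q, cochran_q_p = x$cochran$p
  )
}

#' Plot the radial MR diagnostic
#'
#' Ratio estimates times square-root weight against square-root weight,
#' with the fitted radial slope through the origin and outliers
#' highlighted.
#'
#' @param object an `mr_radial`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot mr_radial
#' @export
autoplot.mr_radial <- function(object, ...) {
  d <- object$snps
  d$y <- d$ratio * sqrt(d$weight)
  d$x <- sqrt(d$weight)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = object$beta, intercept = 0,
                         linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outlier)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(sqrt(w[j])),
                  y = expression(hat(r)[j] * sqrt(w[j])),
                  colour = "Outlier") +
    ggplot2::theme_minimal()
}

#' Plot the piecewise-linear causal curve
#'
#' Cumulative log odds ratio of the outcome across the exposure range,
#' anchored at the reference exposure, with its pointwise confidence
#' band.
#'
#' @param object an `mr_nonlinear`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot mr_nonlinear
#' @export
autoplot.mr_nonlinear <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$hours,
                                             y = .data$log_or)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                      ymax = .data$ci_hi),
                         alpha = 0.15) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = object$reference,
                        linetype = "dotted") +
    ggplot2::labs(x = "Sleep duration (h)",
                  y = "Cumulative log OR vs reference") +
    ggplot2::theme_minimal()
}

#' Forest plot of MR estimates
#'
#' @param estimates tibble of glanced estimates (needs `method`, `or`,
#'   `or_low`, `or_high`; an optional `outcome` column facets the plot).
#' @return A ggplot object.
#' @export
plot_forest <- function(estimates) {
  p <- ggplot2::ggplot(estimates,
                       ggplot2::aes(x = .data$or, y = .data$method)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$or_low,
                                          xmax = .data$or_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
  if ("outcome" %in% names(estimates)) {
    p <- p + ggplot2::facet_wrap(~outcome)
  }
  p
}
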