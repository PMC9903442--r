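#' Instrument-free exposure residuals
#'
#' Residuals of the exposure after regressing out the genetic risk score
#' (and, optionally, covariates). Stratifying on these residuals rather
#' than on the raw exposure avoids the collider bias that exposure
#' stratification would induce in MR.
#'
#' @inheritParams mr_two_stage
#' @return numeric vector of residuals, same length as `nrow(data)`.
#' @export
iv_free_exposure <- function(data, exposure = "sleep_hours", score = "grs",
                             covariates = NULL) {
  s <- data[[score]]
  if (is.null(s)) abort("`score` column not found.")
  if (sd(s) == 0) abort("Score is constant; residuals undefined.")
  x <- as.numeric(data[[exposure]])
  X <- cbind(design_matrix(data, covariates), score = s)
  stats::lm.fit(X, x)$residuals
}

#' Assign equal-count strata from residuals
#'
#' Quantile bins of the instrument-free residual with counts within one
#' of `n / k`; ties are broken by stable input order, so the assignment
#' is deterministic for a given input vector.
#'
#' @param residuals numeric vector from [iv_free_exposure()].
#' @param k number of strata (default 3).
#' @return integer vector of stratum indices in `1:k` (1 = lowest
#'   residuals).
#' @export
stratify_residuals <- function(residuals, k = 3L) {
  n <- length(residuals)
  if (k < 2L) abort("`k` must be >= 2.")
  if (n < k) abort("More strata than observations.")
  if (n < 10L * k) {
    warn("Fewer than 10 participants per stratum; estimates will be unstable.")
  }
  if (length(unique(residuals)) < k) {
    abort("Fewer distinct residual values than strata.")
  }
  r <- rank(residuals, ties.method = "first")
  as.integer(floor((r - 1) * k / n) + 1L)
}

#' Localized average causal effects per stratum
#'
#' Runs the two-stage estimator of [mr_two_stage()] within each stratum
#' (using the global genetic risk score), giving the gradient of the
#' causal curve — the localized average causal effect, LACE — in log-odds
#' per hour, together with the exposure mean and range in the stratum.
#'
#' @inheritParams mr_two_stage
#' @param strata integer stratum assignments from [stratify_residuals()].
#' @return Tibble with one row per stratum: `stratum`, `n`,
#'   `exposure_mean`, `exposure_min`, `exposure_max`, `beta`, `se`,
#'   `ci_lo`, `ci_hi`, `p`.
#' @export
lace_per_stratum <- function(data, strata, outcome,
                             exposure = "sleep_hours", score = "grs",
                             covariates = NULL) {
  ks <- sort(unique(strata))
  rows <- purrr::map(ks, function(s) {
    d <- data[strata == s, , drop = FALSE]
    x <- d[[exposure]]
    y <- d[[outcome]]
    if (length(unique(x)) < 2L) {
      abort(sprintf("Stratum %d has < 2 distinct exposure values.", s))
    }
    if (length(unique(as.numeric(y))) < 2L) {
      abort(sprintf("Stratum %d lacks both outcome classes.", s))
    }
    fit <- mr_two_stage(d, outcome, exposure, score, covariates)
    tibble(stratum = s, n = nrow(d),
           exposure_mean = mean(x), exposure_min = min(x),
           exposure_max = max(x),
           beta = fit$beta, se = fit$se,
           ci_lo = fit$ci_lo, ci_hi = fit$ci_hi, p = fit$p)
  })
  dplyr::bind_rows(rows)
}

#' Quadratic test for nonlinearity across strata
#'
#' Fixed-effect (inverse-variance-weighted) meta-regression of the LACE
#' estimates on the stratum exposure positions; the Wald p-value of the
#' trend coefficient, with a normal reference, tests whether the causal
#' gradient changes with exposure — the signature of nonlinearity.
#'
#' @param strata stratum tibble from [lace_per_stratum()].
#' @param x_position `"mean"` uses the observed stratum exposure mean,
#'   `"midpoint"` the midpoint of the stratum exposure range.
#' @return One-row tibble: `trend_beta`, `trend_se`, `p`.
#' @export
quadratic_test <- function(strata, x_position = c("mean", "midpoint")) {
  x_position <- match.arg(x_position)
  if (nrow(strata) < 3L) abort("Quadratic test needs >= 3 strata.")
  if (any(strata$se <= 0)) abort("Stratum SEs must be > 0.")
  x <- if (x_position == "mean") strata$exposure_mean else {
    (strata$exposure_min + strata$exposure_max) / 2
  }
  w <- 1 / strata$se^2
  X <- cbind(1, x)
  XtWX <- crossprod(X * sqrt(w))
  cov_fe <- solve(XtWX)
  coefs <- cov_fe %*% crossprod(X * w, strata$beta)
  z <- coefs[2] / sqrt(cov_fe[2, 2])
  tibble(trend_beta = coefs[2], trend_se = sqrt(cov_fe[2, 2]),
         p = 2 * pnorm(-abs(z)))
}

#' Cochran Q heterogeneity test across strata
#'
#' `Q = sum w_s (beta_s - beta_pooled)^2` with `w_s = 1 / se_s^2` and the
#' inverse-variance-weighted pooled LACE; referred to chi-squared(k - 1).
#' Heterogeneous stratum effects indicate a non-constant causal gradient.
#'
#' @param strata stratum tibble from [lace_per_stratum()].
#' @return One-row tibble: `q`, `df`, `p`.
#' @export
cochran_q_strata <- function(strata) {
  if (nrow(strata) < 2L) abort("Cochran Q needs >= 2 strata.")
  if (any(strata$se <= 0)) abort("Stratum SEs must be > 0.")
  w <- 1 / strata$se^2
  pooled <- sum(w * strata$beta) / sum(w)
  q <- sum(w * (strata$beta - pooled)^2)
  df <- nrow(strata) - 1L
  tibble(q = q, df = df, p = pchisq(q, df, lower.tail = FALSE))
}

#' Continuous piecewise-linear causal curve from stratum slopes
#'
#' Integrates the stratum LACE slopes into a continuous piecewise-linear
#' cumulative log odds ratio over the exposure range, anchored at zero at
#' the reference exposure. The pointwise confidence band accumulates the
#' slope variances along the path from the reference.
#'
#' @param strata stratum tibble from [lace_per_stratum()], ordered by
#'   exposure (checked).
#' @param boundaries increasing vector of segment boundaries, one more
#'   than the number of strata. Default: overall exposure range split at
#'   midpoints between consecutive stratum exposure means.
#' @param reference exposure value (hours) where the curve equals zero.
#' @return Tibble of curve coordinates: `hours`, `log_or`, `ci_lo`,
#'   `ci_hi` at every boundary plus the reference point.
#' @export
piecewise_curve <- function(strata, boundaries = NULL, reference = 7) {
  if (is.unsorted(strata$exposure_mean, strictly = TRUE)) {
    abort("Strata must be ordered by increasing exposure mean.")
  }
  k <- nrow(strata)
  boundaries <- boundaries %||% c(
    min(strata$exposure_min),
    (strata$exposure_mean[-k] + strata$exposure_mean[-1]) / 2,
    max(strata$exposure_max)
  )
  if (length(boundaries) != k + 1L || is.unsorted(boundaries, strictly = TRUE)) {
    abort("`boundaries` must be strictly increasing with length k + 1.")
  }
  if (reference < boundaries[1] || reference > boundaries[k + 1]) {
    abort("`reference` must lie within the boundary range.")
  }
  grid <- sort(unique(c(boundaries, reference)))
  slope_at <- function(h) {
    i <- findInterval(h, boundaries, rightmost.closed = TRUE,
                      all.inside = TRUE)
    list(beta = strata$beta[i], var = strata$se[i]^2)
  }
  value <- vapply(grid, function(h) {
    lo <- min(h, reference); hi <- max(h, reference)
    pts <- sort(unique(c(lo, hi, boundaries[boundaries > lo & boundaries < hi])))
    if (length(pts) < 2) return(0)
    mids <- (pts[-1] + pts[-length(pts)]) / 2
    seg <- slope_at(mids)
    v <- sum(seg$beta * diff(pts))
    if (h < reference) -v else v
  }, numeric(1))
  variance <- vapply(grid, function(h) {
    lo <- min(h, reference); hi <- max(h, reference)
    pts <- sort(unique(c(lo, hi, boundaries[boundaries > lo & boundaries < hi])))
    if (length(pts) < 2) return(0)
    mids <- (pts[-1] + pts[-length(pts)]) / 2
    seg <- slope_at(mids)
    sum(seg$var * diff(pts)^2)
  }, numeric(1))
  tibble(hours = grid, log_or = value,
         ci_lo = value - 1.96 * sqrt(variance),
         ci_hi = value + 1.96 * sqrt(variance))
}

# Descriptive shape label from the sign pattern of significant LACEs.
shape_label <- function(strata, alpha = 0.05) {
  sig <- strata$p < alpha
  sgn <- sign(strata$beta)
  first <- sgn[1] * sig[1]
  last <- sgn[nrow(strata)] * sig[nrow(strata)]
  if (first < 0 && last <= 0) "L-shaped"
  else if (first < 0 && last > 0) "U-shaped"
  else if (first > 0 && last < 0) "inverse-U-shaped"
  else if (all(!sig)) "flat"
  else "monotonic"
}

#' Piecewise-linear nonlinear MR
#'
#' Full nonlinear MR procedure: (1) compute instrument-free exposure
#' residuals, (2) split the sample into `k` equal-count strata on the
#' residuals, (3) estimate a localized average causal effect (LACE) in
#' each stratum by two-stage MR with the global score, (4) test
#' nonlinearity with the quadratic (trend) and Cochran Q tests, and
#' (5) assemble the continuous piecewise-linear causal curve.
#'
#' @inheritParams mr_two_stage
#' @param k number of residual strata (default 3).
#' @param reference exposure anchoring the curve at zero (default 7 h).
#' @param residual_covariates include `covariates` in the residual
#'   regression too (default `TRUE`); `FALSE` regresses on the score
#'   alone.
#' @param x_position passed to [quadratic_test()].
#' @return An object of class `mr_nonlinear`: list with `strata` (tibble),
#'   `quadratic` (tibble), `cochran` (tibble), `curve` (tibble),
#'   `reference`, `k`, `shape` (descriptive label, not a test statistic).
#' @examples
#' sim <- simulate_cohort(sim_config(n_participants = 5000, seed = 11))
#' dat <- assemble_analysis(sim$cohort, sim$genotypes, sim$instruments)
#' fit <- mr_nonlinear(dat, "hypertriglyceridemia",
#'                     covariates = c("age", "sex"))
#' tidy(fit)
#' @export
mr_nonlinear <- function(data, outcome, exposure = "sleep_hours",
                         score = "grs", covariates = NULL, k = 3L,
                         reference = 7, residual_covariates = TRUE,
                         x_position = "mean") {
  res <- iv_free_exposure(
    data, exposure, score,
    covariates = if (residual_covariates) covariates else NULL)
  strata_id <- stratify_residuals(res, k)
  strata <- lace_per_stratum(data, strata_id, outcome, exposure, score,
                             covariates)
  strata <- strata[order(strata$exposure_mean), ]
  quad <- quadratic_test(strata, x_position)
  coq <- cochran_q_strata(strata)
  curve <- piecewise_curve(strata, reference = reference)
  structure(
    list(strata = strata, quadratic = quad, cochran = coq, curve = curve,
         reference = reference, k = k, outcome = outcome,
         shape = shape_label(strata)),
    class = "mr_nonlinear"
  )
}

#' @export
print.mr_nonlinear <- function(x, ...) {
  cat(sprintf("<mr_nonlinear> outcome '%s', %d strata, shape: %s\n",
              x$outcome, x$k, x$shape))
  print(x$strata)
  cat(sprintf("Quadratic p = %.3g; Cochran Q = %.3g (p = %.3g)\n",
              x$quadratic$p, x$cochran$q, x$cochran$p))
  invisible(x)
}
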