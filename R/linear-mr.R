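#' Two-stage (predictor substitution) MR estimate
#'
#' Stage one regresses the exposure on the genetic risk score plus
#' covariates by ordinary least squares; stage two regresses the outcome
#' on the stage-one fitted exposure plus the same covariates — logistic
#' for a binary outcome (the default, yielding log odds ratios per
#' exposure unit), linear for a continuous outcome. Standard errors are
#' the conventional model-based ones from stage two.
#'
#' @param data data frame holding all columns.
#' @param outcome outcome column name (binary 0/1/logical, or numeric for
#'   `family = "gaussian"`).
#' @param exposure exposure column name (sleep duration in hours).
#' @param score instrument score column name.
#' @param covariates optional character vector of covariate columns used
#'   in both stages.
#' @param family `"binomial"` (default) or `"gaussian"`.
#' @return An `mr_fit` object (see [tidy.mr_fit()]); `scale` is
#'   `"per_hour"` as the exposure is in hours.
#' @examples
#' sim <- simulate_cohort(sim_config(n_participants = 2000, seed = 3))
#' dat <- dplyr::bind_cols(
#'   compute_grs(sim$genotypes, sim$instruments),
#'   sim$cohort[-1], derive_components(sim$cohort)[-1])
#' mr_two_stage(dat, "central_obesity", covariates = c("age", "sex"))
#' @export
mr_two_stage <- function(data, outcome, exposure = "sleep_hours",
                         score = "grs", covariates = NULL,
                         family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  s <- data[[score]]
  if (is.null(s)) abort("`score` column not found.")
  if (sd(s) == 0) abort("Score is constant; MR estimate undefined.")
  y <- as.numeric(data[[outcome]])
  x <- as.numeric(data[[exposure]])
  X0 <- design_matrix(data, covariates)
  stage1 <- fast_lm(cbind(X0, score = s), x)
  X2 <- cbind(X0, fitted_exposure = stage1$fitted)
  fit <- if (family == "binomial") fast_logit(X2, y) else fast_lm(X2, y)
  k <- ncol(X2)
  new_mr_fit(
    "two_stage", beta = fit$coef[[k]], se = fit$se[[k]],
    scale = "per_hour", nobs = length(y),
    extra = list(first_stage_beta = stage1$coef[["score"]],
                 first_stage_se = stage1$se[["score"]],
                 family = family)
  )
}

#' Per-SNP summary statistics within the cohort
#'
#' For each instrument SNP, estimates the SNP-exposure association by
#' linear regression of sleep on dosage (plus covariates) and the
#' SNP-outcome association by logistic regression of the outcome on
#' dosage (plus covariates). These feed the summary-statistic estimators
#' [mr_ivw()], [mr_weighted_median()], [mr_egger()] and [mr_radial()].
#'
#' @inheritParams mr_two_stage
#' @param genotypes dosage table with one column per instrument SNP.
#' @param instruments instrument tibble (`snp_id` column used).
#' @return Tibble with one row per SNP: `snp_id`, `beta_gx`, `se_gx`
#'   (exposure units per allele), `beta_gy`, `se_gy` (log-odds per
#'   allele), `n`. Monomorphic SNPs are dropped with a warning.
#' @export
snp_summary_stats <- function(data, genotypes, instruments, outcome,
                              exposure = "sleep_hours", covariates = NULL) {
  y <- as.numeric(data[[outcome]])
  x <- as.numeric(data[[exposure]])
  X0 <- design_matrix(data, covariates)
  k <- ncol(X0) + 1L
  rows <- purrr::map(instruments$snp_id, function(id) {
    g <- genotypes[[id]]
    if (is.null(g)) abort(paste0("Genotype table lacks SNP: ", id))
    if (sd(g) == 0) {
      warn(paste0("Dropping monomorphic SNP: ", id))
      return(NULL)
    }
    X <- cbind(X0, dosage = as.numeric(g))
    fx <- fast_lm(X, x)
    fy <- fast_logit(X, y)
    tibble(snp_id = id,
           beta_gx = fx$coef[[k]], se_gx = fx$se[[k]],
           beta_gy = fy$coef[[k]], se_gy = fy$se[[k]],
           n = length(y))
  })
  dplyr::bind_rows(rows)
}

check_summary_stats <- function(ss, min_snps = 1L) {
  need <- c("beta_gx", "se_gx", "beta_gy", "se_gy")
  missing <- setdiff(need, names(ss))
  if (length(missing)) {
    abort(paste0("Summary stats lack column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(ss) < min_snps) {
    abort(sprintf("At least %d SNP(s) required, got %d.", min_snps, nrow(ss)))
  }
  if (any(ss$se_gx <= 0) || any(ss$se_gy <= 0)) abort("SEs must be > 0.")
  invisible(ss)
}

#' Inverse-variance-weighted MR estimate
#'
#' Weighted mean of per-SNP Wald ratios `beta_gy / beta_gx` with
#' first-order weights `beta_gx^2 / se_gy^2`. The standard error is
#' inflated multiplicatively by `sqrt(Q / (J - 1))` whenever the Cochran Q
#' heterogeneity statistic exceeds its degrees of freedom (multiplicative
#' random-effects model).
#'
#' @param ss summary-statistic tibble from [snp_summary_stats()].
#' @param scale scale label carried on the estimate (exposure units of
#'   `beta_gx`; `"per_hour"` when stage-one betas are per hour).
#' @return An `mr_fit` with extras `q`, `q_df`, `q_p`.
#' @export
mr_ivw <- function(ss, scale = "per_hour") {
  check_summary_stats(ss, 1L)
  if (any(ss$beta_gx == 0)) abort("beta_gx = 0 gives an undefined ratio.")
  r <- ss$beta_gy / ss$beta_gx
  w <- ss$beta_gx^2 / ss$se_gy^2
  beta <- sum(w * r) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  j <- nrow(ss)
  q <- sum(w * (r - beta)^2)
  infl <- if (j > 1) max(1, sqrt(q / (j - 1))) else 1
  se <- se_fixed * infl
  new_mr_fit("ivw", beta, se, scale = scale, n_snps = j,
             extra = list(q = q, q_df = j - 1L,
                          q_p = if (j > 1) pchisq(q, j - 1, lower.tail = FALSE)
                                else NA_real_))
}

# Weighted median of values x under weights w: order by x, interpolate the
# standardized cumulative weight (midpoint rule) at 50%.
weighted_median_value <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cum <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= cum[1]) return(x[1])
  if (0.5 >= cum[length(cum)]) return(x[length(x)])
  approx(cum, x, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median MR estimate
#'
#' The weighted median of the per-SNP Wald ratios under inverse-variance
#' weights, consistent when at least half the weight comes from valid
#' instruments. The standard error is obtained by parametric bootstrap:
#' `beta_gx` and `beta_gy` are resampled from normal distributions with
#' their estimated SEs and the weighted median recomputed.
#'
#' @inheritParams mr_ivw
#' @param n_boot number of bootstrap draws (default 1000).
#' @param seed seed for the bootstrap (required, for reproducibility).
#' @return An `mr_fit`.
#' @export
mr_weighted_median <- function(ss, n_boot = 1000L, seed, scale = "per_hour") {
  check_summary_stats(ss, 1L)
  if (missing(seed)) abort("`seed` is required for the bootstrap SE.")
  if (n_boot < 100L) abort("`n_boot` must be >= 100.")
  est <- function(bgx, bgy) {
    r <- bgy / bgx
    w <- bgx^2 / ss$se_gy^2
    weighted_median_value(r, w)
  }
  beta <- est(ss$beta_gx, ss$beta_gy)
  set.seed(seed)
  j <- nrow(ss)
  boot <- vapply(seq_len(n_boot), function(i) {
    est(rnorm(j, ss$beta_gx, ss$se_gx), rnorm(j, ss$beta_gy, ss$se_gy))
  }, numeric(1))
  new_mr_fit("weighted_median", beta, sd(boot), scale = scale, n_snps = j,
             extra = list(n_boot = n_boot, seed = seed))
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of SNP-outcome associations on
#' SNP-exposure associations with an unconstrained intercept, weights
#' `1 / se_gy^2`, after orienting every SNP to a positive exposure
#' association. The slope is the causal estimate; an intercept different
#' from zero indicates directional horizontal pleiotropy. SEs use a
#' multiplicative dispersion floored at 1 and a t reference with J - 2
#' degrees of freedom.
#'
#' @inheritParams mr_ivw
#' @return An `mr_fit` with extras `egger_intercept`, `intercept_se`,
#'   `intercept_p`.
#' @export
mr_egger <- function(ss, scale = "per_hour") {
  check_summary_stats(ss, 2L)
  flip <- sign(ss$beta_gx)
  bgx <- ss$beta_gx * flip
  bgy <- ss$beta_gy * flip
  if (sd(bgx) == 0) abort("No spread in beta_gx; Egger slope undefined.")
  w <- 1 / ss$se_gy^2
  j <- nrow(ss)
  X <- cbind(1, bgx) * sqrt(w)
  fitw <- stats::lm.fit(X, bgy * sqrt(w))
  coefs <- fitw$coefficients
  df <- j - 2L
  R <- fitw$qr$qr[1:2, 1:2]; R[lower.tri(R)] <- 0
  cov_un <- chol2inv(R)
  if (df > 0) {
    sigma <- max(1, sqrt(sum(fitw$residuals^2) / df))
    se <- sqrt(diag(cov_un)) * sigma
    pv <- 2 * stats::pt(-abs(coefs / se), df)
  } else {
    se <- rep(NA_real_, 2)
    pv <- rep(NA_real_, 2)
  }
  new_mr_fit("egger", beta = coefs[[2]], se = se[[2]], p = pv[[2]],
             scale = scale, n_snps = j,
             extra = list(egger_intercept = coefs[[1]],
                          intercept_se = se[[1]], intercept_p = pv[[1]]))
}

#' Radial MR with modified second-order weights and outlier detection
#'
#' Radial (Galbraith) reformulation of IVW: regression through the origin
#' of `ratio * sqrt(w)` on `sqrt(w)`. Weights are modified second-order,
#' `w_j = beta_gx^2 / (se_gy^2 + beta^2 * se_gx^2)`, iterated from the
#' first-order IVW estimate until the global slope changes by less than
#' `tol`. Each SNP's contribution to the global Cochran Q is referred to
#' a chi-squared(1) distribution; SNPs with `q_p < alpha` are flagged as
#' outliers (default `alpha = 0.05 / J`).
#'
#' @inheritParams mr_ivw
#' @param alpha per-SNP flagging level; default `0.05 / nrow(ss)`.
#' @param tol convergence tolerance on the slope.
#' @param max_iter maximum weight iterations.
#' @return An object of class `mr_radial`: per-SNP tibble (`snp_id`,
#'   `ratio`, `weight`, `q_contribution`, `q_pvalue`, `outlier`) plus
#'   global slope/SE, `global_q`, `q_p`, `alpha`, iteration count.
#' @export
mr_radial <- function(ss, alpha = NULL, scale = "per_hour",
                      tol = 1e-8, max_iter = 100L) {
  check_summary_stats(ss, 2L)
  if (any(ss$beta_gx == 0)) abort("beta_gx = 0 gives an undefined ratio.")
  alpha <- alpha %||% (0.05 / nrow(ss))
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  r <- ss$beta_gy / ss$beta_gx
  w1 <- ss$beta_gx^2 / ss$se_gy^2
  beta <- sum(w1 * r) / sum(w1)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    w <- ss$beta_gx^2 / (ss$se_gy^2 + beta^2 * ss$se_gx^2)
    beta_new <- sum(w * r) / sum(w)
    if (abs(beta_new - beta) < tol) { beta <- beta_new; break }
    beta <- beta_new
    if (iter >= max_iter) {
      abort(sprintf(
        "Radial estimator did not converge in %d iterations (last slope %.6g).",
        max_iter, beta), class = "sleepmr_convergence_error")
    }
  }
  w <- ss$beta_gx^2 / (ss$se_gy^2 + beta^2 * ss$se_gx^2)
  qj <- w * (r - beta)^2
  qp <- pchisq(qj, 1, lower.tail = FALSE)
  snps <- tibble(
    snp_id = ss$snp_id %||% sprintf("snp_%d", seq_len(nrow(ss))),
    ratio = r, weight = w, q_contribution = qj, q_pvalue = qp,
    outlier = qp < alpha
  )
  structure(
    list(snps = snps, beta = beta, se = sqrt(1 / sum(w)),
         global_q = sum(qj), q_df = nrow(ss) - 1L,
         q_p = pchisq(sum(qj), nrow(ss) - 1L, lower.tail = FALSE),
         alpha = alpha, iterations = iter, scale = scale),
    class = "mr_radial"
  )
}

#' @export
print.mr_radial <- function(x, ...) {
  cat(sprintf(
    "<mr_radial> slope %.4g (SE %.3g), Q = %.3g (df %d, p = %.3g)\n",
    x$beta, x$se, x$global_q, x$q_df, x$q_p))
  cat(sprintf("  %d / %d SNPs flagged as outliers at alpha = %.3g\n",
              sum(x$snps$outlier), nrow(x$snps), x$alpha))
  invisible(x)
}

#' Rescale an MR estimate between reporting scales
#'
#' Converts between per-minute and per-hour log odds ratios (factor 60)
#' and to the per-doubling-of-genetic-liability scale for binary sleep
#' traits (factor `log(2) = 0.693`). Beta and SE are multiplied by the
#' factor, the confidence interval is recomputed, and the p-value is
#' unchanged (the Wald z is scale-invariant).
#'
#' @param est an `mr_fit`.
#' @param to target scale: `"per_hour"`, `"per_minute"`, `"per_doubling"`.
#' @return The rescaled `mr_fit`.
#' @examples
#' est <- sleepmr:::new_mr_fit("ivw", 0.001, 0.0005, scale = "per_minute")
#' rescale_estimate(est, "per_hour")$beta  # 0.06
#' @export
rescale_estimate <- function(est, to) {
  stopifnot(inherits(est, "mr_fit"))
  from <- est$scale
  if (from == to) return(est)
  factor <- if (from == "per_minute" && to == "per_hour") {
    60
  } else if (from == "per_hour" && to == "per_minute") {
    1 / 60
  } else if (to == "per_doubling" && from %in% c("per_unit_score")) {
    log(2)
  } else if (from == "per_doubling" && to == "per_unit_score") {
    1 / log(2)
  } else {
    abort(sprintf("Unsupported scale transition: %s -> %s", from, to))
  }
  est$beta <- est$beta * factor
  est$se <- est$se * factor
  est$ci_lo <- est$beta - 1.96 * est$se
  est$ci_hi <- est$beta + 1.96 * est$se
  est$scale <- to
  est
}

#' Regress an outcome directly on a weighted genetic risk score
#'
#' Complementary analysis for binary sleep traits (genetic liability to
#' short or long sleep): logistic regression of the outcome on the
#' weighted score plus covariates, with the log odds ratio rescaled by
#' `log(2)` to a per-doubling-of-genetic-liability interpretation. The
#' score weights are assumed to be on the log-liability scale of the
#' binary sleep trait.
#'
#' @inheritParams mr_two_stage
#' @param per_doubling rescale to per-doubling (default `TRUE`)?
#' @return An `mr_fit` with `scale = "per_doubling"` (or
#'   `"per_unit_score"` when `per_doubling = FALSE`).
#' @export
grs_outcome_regression <- function(data, outcome, score = "grs",
                                   covariates = NULL, per_doubling = TRUE) {
  s <- as.numeric(data[[score]])
  if (sd(s) == 0) abort("Score is constant; regression undefined.")
  y <- as.numeric(data[[outcome]])
  X <- cbind(design_matrix(data, covariates), score = s)
  fit <- fast_logit(X, y)
  k <- ncol(X)
  est <- new_mr_fit("grs_regression", fit$coef[[k]], fit$se[[k]],
                    scale = "per_unit_score", nobs = length(y))
  if (per_doubling) rescale_estimate(est, "per_doubling") else est
}

#' Monte-Carlo power for the two-stage linear MR design
#'
#' For each candidate causal slope, simulates cohorts under a linear
#' dose-response with that slope and records how often the two-stage
#' estimate rejects at level `alpha`.
#'
#' @param config a [sim_config()]; its `dose_response` is replaced by a
#'   linear curve at each grid value.
#' @param effect_grid numeric vector of causal slopes (log-odds per hour).
#' @param alpha test level (default 0.05).
#' @param n_reps replicates per effect size (>= 100 recommended; smaller
#'   values allowed for quick exploration).
#' @param outcome which derived component to analyse.
#' @param covariates covariates passed to [mr_two_stage()].
#' @return Tibble: `effect`, `power`, `mc_se`, `n_reps`.
#' @export
mr_power <- function(config, effect_grid, alpha = 0.05, n_reps = 100L,
                     outcome = "central_obesity",
                     covariates = c("age", "sex")) {
  stopifnot(inherits(config, "sim_config"))
  rows <- purrr::map(effect_grid, function(eff) {
    rej <- vapply(seq_len(n_reps), function(i) {
      cfg <- config
      cfg$dose_response <- dose_response("linear", slope = eff)
      cfg$seed <- config$seed + 7919L * which(effect_grid == eff) + i
      sim <- simulate_cohort(cfg)
      dat <- assemble_analysis(sim$cohort, sim$genotypes, sim$instruments)
      fit <- mr_two_stage(dat, outcome, covariates = covariates)
      fit$p < alpha
    }, logical(1))
    p_hat <- mean(rej)
    tibble(effect = eff, power = p_hat,
           mc_se = sqrt(p_hat * (1 - p_hat) / n_reps), n_reps = n_reps)
  })
  dplyr::bind_rows(rows)
}
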