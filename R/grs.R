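#' Compute a genetic risk score from dosages and an instrument table
#'
#' The unweighted score counts sleep-duration-increasing alleles: any SNP
#' whose exposure effect is negative is re-oriented (`dosage -> 2 - dosage`)
#' before summing, so a higher score always means genetically longer sleep.
#' The weighted score is the plain dot product of dosages with the per-SNP
#' exposure effects (orientation is then carried by the weight's sign).
#'
#' @param genotypes data frame of effect-allele dosages in `[0, 2]`, one
#'   column per SNP; non-SNP columns (e.g. `participant_id`) pass through.
#' @param instruments instrument tibble with `snp_id` and an effect column
#'   (`beta_exposure_minutes` by default).
#' @param weighted logical; weight dosages by per-SNP effects?
#' @param beta_col name of the effect column used for orientation/weights.
#' @return A tibble: pass-through id columns plus `grs`. The number of
#'   SNPs used is attached as attribute `n_snps_used`.
#' @examples
#' geno <- tibble::tibble(snp1 = c(0, 1), snp2 = c(2, 1))
#' ins <- tibble::tibble(snp_id = c("snp1", "snp2"),
#'                       beta_exposure_minutes = c(1.5, -2))
#' compute_grs(geno, ins)
#' @export
compute_grs <- function(genotypes, instruments, weighted = FALSE,
                        beta_col = "beta_exposure_minutes") {
  missing <- setdiff(instruments$snp_id, names(genotypes))
  if (length(missing)) {
    abort(paste0("Genotype table lacks instrument SNP(s): ",
                 paste(missing, collapse = ", ")))
  }
  G <- as.matrix(genotypes[instruments$snp_id])
  if (anyNA(G) || min(G) < 0 || max(G) > 2) {
    abort("Dosages must be non-missing and within [0, 2].")
  }
  beta <- instruments[[beta_col]]
  if (weighted) {
    score <- as.numeric(G %*% beta)
  } else {
    flip <- beta < 0
    if (any(flip)) G[, flip] <- 2 - G[, flip, drop = FALSE]
    score <- rowSums(G)
  }
  ids <- setdiff(names(genotypes), instruments$snp_id)
  out <- dplyr::bind_cols(genotypes[ids], tibble(grs = score))
  attr(out, "n_snps_used") <- nrow(instruments)
  out
}

#' Instrument strength: incremental R-squared and partial F
#'
#' Quantifies how much sleep-duration variance the genetic risk score
#' explains beyond the covariates, by comparing residual variance between
#' nested linear models, and the corresponding partial F statistic for the
#' score term. In the univariate case the identity
#' `F = (n - 2) r2 / (1 - r2)` holds.
#'
#' @param data data frame with the score, exposure and covariate columns.
#' @param score,exposure column names (score = GRS, exposure = sleep hours).
#' @param covariates optional character vector of covariate column names.
#' @return One-row tibble: `r2`, `f_stat`, `n`, `n_covariates`.
#' @export
instrument_strength <- function(data, score = "grs",
                                exposure = "sleep_hours",
                                covariates = NULL) {
  s <- data[[score]]
  y <- data[[exposure]]
  if (is.null(s) || is.null(y)) abort("`score`/`exposure` column not found.")
  if (sd(s) == 0) abort("Score is constant; strength undefined.")
  X0 <- design_matrix(data, covariates)
  f0 <- stats::lm.fit(X0, y)
  f1 <- stats::lm.fit(cbind(X0, score = s), y)
  rss0 <- sum(f0$residuals^2)
  rss1 <- sum(f1$residuals^2)
  n <- length(y)
  df1 <- n - f1$rank
  r2 <- (rss0 - rss1) / rss0
  f_stat <- (rss0 - rss1) / (rss1 / df1)
  tibble(r2 = r2, f_stat = f_stat, n = n,
         n_covariates = length(covariates %||% character(0)))
}

#' Screen covariates for association with the genetic risk score
#'
#' Regresses each candidate confounder on the score (one linear model per
#' covariate) and flags associations below a Bonferroni threshold. A
#' flagged covariate suggests the instrument may violate the exchange-
#' ability assumption and should be adjusted for in sensitivity analyses.
#'
#' @param data data frame holding the score and covariates.
#' @param score score column name.
#' @param covariates character vector of covariate columns (numeric or
#'   0/1 coded).
#' @param alpha significance threshold (default 0.004).
#' @return Tibble with one row per covariate: `covariate`, `beta`, `se`,
#'   `p`, `flagged`. Zero-variance covariates are skipped with a warning.
#' @export
confounder_screen <- function(data, score = "grs", covariates,
                              alpha = 0.004) {
  s <- data[[score]]
  if (is.null(s)) abort("`score` column not found.")
  X <- cbind(1, s)
  rows <- purrr::map(covariates, function(cv) {
    y <- data[[cv]]
    if (is.null(y)) abort(paste0("Covariate not in data: ", cv))
    y <- as.numeric(y)
    if (sd(y) == 0) {
      warn(paste0("Skipping zero-variance covariate: ", cv))
      return(NULL)
    }
    fit <- fast_lm(X, y)
    b <- fit$coef[[2]]; se <- fit$se[[2]]
    tibble(covariate = cv, beta = b, se = se,
           p = 2 * stats::pt(-abs(b / se), fit$df_residual))
  })
  out <- dplyr::bind_rows(rows)
  out$flagged <- out$p < alpha
  attr(out, "alpha") <- alpha
  out
}
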