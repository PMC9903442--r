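# Internal regression helpers built on lm.fit / glm.fit so that the
# Monte-Carlo-heavy paths avoid formula/model-frame overhead.

# Build a numeric design matrix from named covariate columns (factors and
# characters are expanded to dummies); returns matrix with intercept.
design_matrix <- function(data, covariates = NULL) {
  n <- nrow(data)
  if (is.null(covariates) || length(covariates) == 0L) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  missing <- setdiff(covariates, names(data))
  if (length(missing)) {
    abort(paste0("Covariate column(s) not in data: ",
                 paste(missing, collapse = ", ")))
  }
  df <- as.data.frame(data[covariates])
  chr <- vapply(df, is.character, logical(1))
  df[chr] <- lapply(df[chr], factor)
  stats::model.matrix(~ ., df)
}

# Linear regression of y on cbind(X, extra); returns coef/se/p for the
# last `report` columns plus residuals and RSS.
fast_lm <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  p <- fit$rank
  n <- length(y)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - p)
  R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  R[lower.tri(R)] <- 0
  XtX_inv <- chol2inv(R)
  se <- sqrt(diag(XtX_inv) * sigma2)
  keep <- fit$qr$pivot[seq_len(p)]
  coefs <- fit$coefficients[keep]
  list(coef = coefs, se = setNames(se, names(coefs)),
       residuals = fit$residuals, fitted = fit$fitted.values,
       rss = rss, df_residual = n - p)
}

# Logistic regression; returns coef/se/p. Errors on (quasi-)separation.
fast_logit <- function(X, y) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = binomial(), control = list(maxit = 50))
  )
  mu <- fit$fitted.values
  if (!fit$converged || any(mu < 1e-10) || any(mu > 1 - 1e-10)) {
    abort(paste("Logistic stage did not converge (possible perfect",
                "separation); a larger sample may be needed."),
          class = "sleepmr_separation_error")
  }
  p <- fit$rank
  w <- fit$weights
  R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  R[lower.tri(R)] <- 0
  cov_un <- chol2inv(R)
  se <- sqrt(diag(cov_un))
  keep <- fit$qr$pivot[seq_len(p)]
  coefs <- fit$coefficients[keep]
  list(coef = coefs, se = setNames(se, names(coefs)))
}

# One mr_fit record (broom-able container used by all estimators).
new_mr_fit <- function(method, beta, se, p = NULL, scale = "per_hour",
                       n_snps = NA_integer_, nobs = NA_integer_,
                       extra = list()) {
  p <- p %||% 2 * pnorm(-abs(beta / se))
  structure(
    c(list(method = method, beta = beta, se = se,
           ci_lo = beta - 1.96 * se, ci_hi = beta + 1.96 * se,
           p = p, scale = scale, n_snps = n_snps, nobs = nobs),
      extra),
    class = "mr_fit"
  )
}

#' @export
print.mr_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<mr_fit: %s> scale = %s\n", x$method, x$scale))
  cat(sprintf("  log-OR %.*g (SE %.*g), 95%% CI [%.*g, %.*g], p = %.3g\n",
              digits, x$beta, digits, x$se, digits, x$ci_lo,
              digits, x$ci_hi, x$p))
  cat(sprintf("  OR %.*g [%.*g, %.*g]\n", digits, exp(x$beta),
              digits, exp(x$ci_lo), digits, exp(x$ci_hi)))
  if (!is.na(x$n_snps)) cat(sprintf("  n_snps = %d\n", x$n_snps))
  invisible(x)
}
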