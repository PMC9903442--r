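test_that("instrument-free residuals satisfy OLS identities", {
  set.seed(4)
  n <- 500
  d <- tibble::tibble(grs = rnorm(n), age = rnorm(n))
  d$sleep_hours <- 7 + 0.3 * d$grs + 0.1 * d$age + rnorm(n)
  res <- iv_free_exposure(d, covariates = "age")
  expect_lt(abs(mean(res)), 1e-10)
  expect_lt(abs(cor(res, d$grs)), 1e-10)
  # score with zero effect: residuals are just centred sleep
  d2 <- tibble::tibble(grs = rep(c(0, 1), each = 50),
                       sleep_hours = rep(c(6, 8), 50))
  res2 <- iv_free_exposure(d2)
  fit <- lm(sleep_hours ~ grs, d2)
  expect_equal(res2, unname(resid(fit)), tolerance = 1e-12)
})

test_that("stratification gives stable equal-count bins", {
  expect_equal(suppressWarnings(stratify_residuals(1:9, 3)),
               rep(1:3, each = 3))
  set.seed(5)
  r <- rnorm(1000)
  s <- stratify_residuals(r, 3)
  expect_true(all(abs(table(s) - 1000 / 3) < 1))
  expect_identical(s, stratify_residuals(r, 3))        # deterministic
  expect_identical(s, stratify_residuals(r + 5, 3))    # shift-invariant
  expect_warning(stratify_residuals(rnorm(15), 3), "10")
  expect_error(stratify_residuals(rep(1, 100), 3), "distinct")
})

test_that("stratum LACE estimates recover a linear truth", {
  cfg <- sim_config(n_participants = 60000,
                    dose_response = dose_response("linear", slope = -0.2),
                    seed = 19)
  dat <- make_dataset(cfg)$dat
  nl <- mr_nonlinear(dat, "hypertriglyceridemia",
                     covariates = c("age", "sex"))
  # each stratum CI covers the constant true slope
  expect_true(all(nl$strata$ci_lo <= -0.2 & nl$strata$ci_hi >= -0.2))
  expect_true(all(diff(nl$strata$exposure_mean) > 0))
  expect_equal(sum(nl$strata$n), nrow(dat))
})

test_that("degenerate strata raise informative errors", {
  d <- tibble::tibble(grs = rnorm(40), sleep_hours = rep(7, 40),
                      y = rbinom(40, 1, 0.5))
  expect_error(lace_per_stratum(d, rep(1:2, each = 20), "y"),
               "distinct exposure")
  d2 <- tibble::tibble(grs = rnorm(40), sleep_hours = rep(c(6, 8), 20),
                       y = rep(0, 40))
  expect_error(lace_per_stratum(d2, rep(1:2, each = 20), "y"),
               "outcome classes")
})

test_that("quadratic test behaves at its extremes", {
  flat <- tibble::tibble(exposure_mean = c(5, 7, 9),
                         exposure_min = c(4, 6, 8), exposure_max = c(6, 8, 11),
                         beta = c(0.2, 0.2, 0.2), se = c(0.1, 0.1, 0.1))
  out <- quadratic_test(flat)
  expect_equal(out$trend_beta, 0, tolerance = 1e-12)
  expect_equal(out$p, 1)
  steep <- dplyr::mutate(flat, beta = c(-0.5, 0, 0.5), se = 1e-4)
  expect_lt(quadratic_test(steep)$p, 1e-10)
  expect_error(quadratic_test(flat[1:2, ]), "3 strata")
})

test_that("Cochran Q across strata matches hand computation", {
  two <- tibble::tibble(beta = c(0, 1), se = c(1, 1))
  out <- cochran_q_strata(two)
  expect_equal(out$q, 0.5)   # pooled mean 0.5, each contributes 0.25
  expect_equal(out$df, 1L)
  same <- tibble::tibble(beta = c(0.3, 0.3, 0.3), se = c(0.2, 0.1, 0.3))
  expect_equal(cochran_q_strata(same)$q, 0)
  expect_equal(cochran_q_strata(same)$p, 1)
  # scale invariance: common rescaling of betas and SEs leaves Q unchanged
  sc <- dplyr::mutate(two, beta = beta * 60, se = se * 60)
  expect_equal(cochran_q_strata(sc)$q, out$q)
  expect_error(cochran_q_strata(dplyr::mutate(two, se = c(0, 1))), "SE")
})

test_that("piecewise curve integrates slopes from the reference", {
  strata <- tibble::tibble(
    stratum = 1:3, exposure_mean = c(5.5, 8, 10),
    exposure_min = c(4, 7, 9), exposure_max = c(7, 9, 11),
    beta = c(-0.3, 0, 0), se = c(0.05, 0.05, 0.05)
  )
  curve <- piecewise_curve(strata, boundaries = c(4, 7, 9, 11),
                           reference = 7)
  expect_equal(curve$log_or[curve$hours == 7], 0)
  expect_equal(curve$log_or[curve$hours == 4], 0.9)  # 3 h at slope -0.3
  expect_equal(curve$log_or[curve$hours == 11], 0)
  # flat slopes give a flat curve at zero
  flat <- dplyr::mutate(strata, beta = 0)
  expect_equal(piecewise_curve(flat, reference = 7)$log_or,
               rep(0, nrow(piecewise_curve(flat, reference = 7))))
  # continuity: no jumps between adjacent grid values beyond slope * width
  d <- diff(curve$log_or) / diff(curve$hours)
  expect_true(all(abs(d) <= 0.3 + 1e-12))
  expect_error(piecewise_curve(strata, boundaries = c(4, 9, 7, 11)),
               "increasing")
})

test_that("nonlinear fit reports strata, tests, curve and tidiers", {
  cfg <- sim_config(n_participants = 8000, seed = 23)
  dat <- make_dataset(cfg)$dat
  nl <- mr_nonlinear(dat, "hypertriglyceridemia",
                     covariates = c("age", "sex"))
  expect_s3_class(nl, "mr_nonlinear")
  expect_equal(nrow(nl$strata), 3L)
  expect_equal(glance(nl)$quadratic_p, nl$quadratic$p)
  expect_equal(nrow(tidy(nl)), 3L)
  expect_s3_class(autoplot(nl), "ggplot")
  # curve anchored at zero at the reference
  expect_equal(nl$curve$log_or[nl$curve$hours == 7], 0)
})
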