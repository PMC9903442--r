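test_that("two-stage slope is exact in the noiseless continuous case", {
  set.seed(2)
  n <- 200
  d <- tibble::tibble(grs = rbinom(n, 20, 0.5))
  d$sleep_hours <- 7 + 0.05 * d$grs + rnorm(n, 0, 0.5)
  d$y <- 2 * d$sleep_hours
  fit <- mr_two_stage(d, "y", family = "gaussian")
  expect_equal(fit$beta, 2, tolerance = 1e-10)
})

test_that("two-stage equals reduced-form over first-stage ratio", {
  set.seed(3)
  n <- 500
  d <- tibble::tibble(
    grs = rnorm(n), age = rnorm(n), sex = sample(c("male", "female"), n, TRUE)
  )
  d$sleep_hours <- 7 + 0.2 * d$grs + 0.1 * d$age + rnorm(n)
  d$y <- 1 - 0.3 * d$sleep_hours + 0.2 * d$age + rnorm(n)
  fit <- mr_two_stage(d, "y", covariates = c("age", "sex"),
                      family = "gaussian")
  reduced <- lm(y ~ age + sex + grs, d)
  first <- lm(sleep_hours ~ age + sex + grs, d)
  expect_equal(fit$beta, coef(reduced)[["grs"]] / coef(first)[["grs"]],
               tolerance = 1e-8)
})

test_that("per-SNP summary statistics recover planted effects", {
  set.seed(5)
  n <- 8000
  g1 <- rbinom(n, 2, 0.3); g2 <- rbinom(n, 2, 0.5)
  sleep <- 7 + (2 / 60) * g1 + rnorm(n)   # 2 minutes per allele
  y <- rbinom(n, 1, plogis(-1 + 0.1 * g2))
  d <- tibble::tibble(sleep_hours = sleep, y = y)
  geno <- tibble::tibble(s1 = g1, s2 = g2, s3 = rep(0L, n))
  ins <- tibble::tibble(snp_id = c("s1", "s2", "s3"),
                        beta_exposure_minutes = c(2, 0, 1))
  expect_warning(ss <- snp_summary_stats(d, geno, ins, "y"), "monomorphic")
  expect_equal(nrow(ss), 2L)
  # planted exposure effect recovered within its CI
  expect_lt(abs(ss$beta_gx[1] - 2 / 60), 1.96 * ss$se_gx[1])
  # SNP unrelated to sleep: association within 3 SE of zero
  expect_lt(abs(ss$beta_gx[2]), 3 * ss$se_gx[2])
  expect_lt(abs(ss$beta_gy[2] - 0.1), 1.96 * ss$se_gy[2])
})

test_that("IVW matches the Wald ratio and hand-computed weighted means", {
  # single SNP: Wald ratio
  ss1 <- make_ss(0.1, 0.02, 0.01)
  fit1 <- mr_ivw(ss1)
  expect_equal(fit1$beta, 0.2)
  # two SNPs, hand-computed: ratios 0.1, 0.2; weights 100, 100
  ss2 <- make_ss(c(0.1, 0.2), c(0.01, 0.04), c(0.01, 0.02))
  fit2 <- mr_ivw(ss2)
  expect_equal(fit2$beta, 0.15)
  expect_equal(fit2$q, 100 * 0.05^2 + 100 * 0.05^2)
  # homogeneous ratios: beta = common ratio, Q = 0
  ss3 <- make_ss(c(0.1, 0.2, 0.4), c(0.03, 0.06, 0.12), c(0.01, 0.02, 0.01))
  fit3 <- mr_ivw(ss3)
  expect_equal(fit3$beta, 0.3)
  expect_equal(fit3$q, 0, tolerance = 1e-20)
  expect_error(mr_ivw(make_ss(0, 0.1, 0.1)), "undefined")
})

test_that("IVW equals fixed-effect meta-analysis of Wald ratios", {
  set.seed(6)
  ss <- make_ss(runif(5, 0.1, 0.3), rnorm(5, 0.05, 0.02),
                runif(5, 0.01, 0.03))
  fit <- mr_ivw(ss)
  # first-order delta-method SEs for the ratios -> inverse-variance pool
  r <- ss$beta_gy / ss$beta_gx
  se_r <- ss$se_gy / abs(ss$beta_gx)
  w <- 1 / se_r^2
  expect_equal(fit$beta, sum(w * r) / sum(w), tolerance = 1e-12)
})

test_that("weighted median follows the cumulative-weight rule", {
  ss1 <- make_ss(0.1, 0.02, 0.01)
  expect_equal(mr_weighted_median(ss1, seed = 1)$beta, 0.2)
  # three SNPs, equal weights, ratios (0.1, 0.2, 0.9) -> 0.2
  ss3 <- make_ss(c(0.1, 0.1, 0.1), c(0.01, 0.02, 0.09), c(0.01, 0.01, 0.01))
  expect_equal(mr_weighted_median(ss3, seed = 1)$beta, 0.2)
  # bracketing: estimate always within the ratio range
  set.seed(9)
  for (i in 1:20) {
    ss <- make_ss(runif(4, 0.05, 0.3), rnorm(4, 0, 0.05),
                  runif(4, 0.005, 0.05))
    est <- mr_weighted_median(ss, seed = i)$beta
    r <- ss$beta_gy / ss$beta_gx
    expect_gte(est, min(r)); expect_lte(est, max(r))
  }
  # bootstrap SE reproducible under a fixed seed
  ss <- make_ss(c(0.1, 0.2, 0.3), c(0.02, 0.05, 0.08),
                c(0.01, 0.02, 0.01), se_gx = c(0.01, 0.01, 0.01))
  expect_identical(mr_weighted_median(ss, seed = 7)$se,
                   mr_weighted_median(ss, seed = 7)$se)
  expect_error(mr_weighted_median(ss), "seed")
})

test_that("MR-Egger reproduces the exact two-point line", {
  ss <- make_ss(c(0.1, 0.2), c(0.01, 0.04), c(1, 1))
  fit <- mr_egger(ss)
  expect_equal(fit$beta, 0.3, tolerance = 1e-12)
  expect_equal(fit$egger_intercept, -0.02, tolerance = 1e-12)
  # homogeneous ratios through the origin: slope = ratio, intercept = 0
  ss0 <- make_ss(c(0.1, 0.2, 0.4), c(0.05, 0.1, 0.2), c(0.01, 0.01, 0.01))
  fit0 <- mr_egger(ss0)
  expect_equal(fit0$beta, 0.5, tolerance = 1e-10)
  expect_equal(fit0$egger_intercept, 0, tolerance = 1e-10)
  expect_error(mr_egger(make_ss(c(0.1, 0.1), c(0.01, 0.02), c(1, 1))),
               "spread")
})

test_that("radial MR flags no outliers under homogeneity and computes Q", {
  ss <- make_ss(c(0.1, 0.2, 0.4), c(0.03, 0.06, 0.12),
                c(0.01, 0.02, 0.01), se_gx = c(0.01, 0.01, 0.01))
  rad <- mr_radial(ss)
  expect_equal(rad$snps$q_contribution, rep(0, 3), tolerance = 1e-16)
  expect_false(any(rad$snps$outlier))
  expect_equal(rad$global_q, sum(rad$snps$q_contribution))
  # default alpha arithmetic at J = 78
  ss78 <- make_ss(runif(78, 0.1, 0.3), rnorm(78, 0.05, 0.01),
                  runif(78, 0.01, 0.03), se_gx = rep(0.01, 78))
  expect_equal(mr_radial(ss78)$alpha, 0.05 / 78)
})

test_that("removing flagged radial outliers never increases global Q", {
  set.seed(12)
  for (i in 1:15) {
    ss <- make_ss(runif(12, 0.1, 0.3),
                  rnorm(12, 0.03, 0.04),  # heterogeneous ratios
                  runif(12, 0.005, 0.02), se_gx = runif(12, 0.005, 0.02))
    rad <- mr_radial(ss, alpha = 0.05)
    if (any(rad$snps$outlier) && sum(!rad$snps$outlier) >= 2) {
      rad2 <- mr_radial(ss[!rad$snps$outlier, ], alpha = 0.05)
      expect_lte(rad2$global_q, rad$global_q)
    }
  }
})

test_that("rescaling moves between scales and round-trips", {
  est <- sleepmr:::new_mr_fit("ivw", 0.001, 0.0005, scale = "per_minute")
  hr <- rescale_estimate(est, "per_hour")
  expect_equal(hr$beta, 0.06)
  expect_equal(hr$se, 0.03)
  expect_equal(hr$p, est$p)  # p unchanged
  back <- rescale_estimate(hr, "per_minute")
  expect_equal(back$beta, est$beta, tolerance = 1e-15)
  dbl <- rescale_estimate(
    sleepmr:::new_mr_fit("grs_regression", 1, 0.1, scale = "per_unit_score"),
    "per_doubling")
  expect_equal(dbl$beta, 0.693, tolerance = 1e-3)
  expect_error(rescale_estimate(hr, "per_doubling"), "transition")
})

test_that("GRS-outcome regression recovers a planted short-sleep effect", {
  set.seed(14)
  n <- 20000
  score <- rnorm(n)  # genetic liability to short sleep
  y <- rbinom(n, 1, plogis(-0.5 + 0.2 * score))
  d <- tibble::tibble(grs = score, y = y)
  fit <- grs_outcome_regression(d, "y")
  expect_equal(fit$scale, "per_doubling")
  expect_gt(exp(fit$beta), 1)  # correct sign
  expect_lt(abs(fit$beta / log(2) - 0.2), 1.96 * fit$se / log(2))
})

test_that("power simulation is sized at the null and rises with effect", {
  cfg <- sim_config(n_participants = 3000, n_snps = 10, seed = 33)
  pow <- mr_power(cfg, effect_grid = c(0, -0.8), alpha = 0.1, n_reps = 25)
  expect_equal(nrow(pow), 2L)
  expect_lt(pow$power[pow$effect == 0], 0.35)
  expect_gte(pow$power[pow$effect == -0.8],
             pow$power[pow$effect == 0])
  expect_true(all(pow$mc_se <= 0.5 / sqrt(25)))
})

test_that("tidiers expose estimates in broom shape", {
  ss <- make_ss(c(0.1, 0.2, 0.3), c(0.02, 0.05, 0.08),
                c(0.01, 0.02, 0.01))
  td <- tidy(mr_ivw(ss))
  expect_named(td, c("method", "term", "estimate", "std.error",
                     "conf.low", "conf.high", "p.value", "scale"))
  expect_equal(nrow(tidy(mr_egger(ss))), 2L)
  gl <- glance(mr_ivw(ss))
  expect_equal(gl$or, exp(td$estimate))
  expect_s3_class(autoplot(mr_radial(ss)), "ggplot")
})
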