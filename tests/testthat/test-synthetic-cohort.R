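test_that("config validation names the offending field", {
  expect_error(sim_config(target_r2 = 0.2), "target_r2")
  expect_error(sim_config(eaf_range = c(0, 0.9)), "eaf_range")
  expect_error(sim_config(n_snps = 0), "n_snps")
  expect_error(sim_config(seed = 2^31), "seed")
})

test_that("single-SNP instrument table has one positive effect", {
  ins <- simulate_instruments(sim_config(n_snps = 1, seed = 2))
  expect_equal(nrow(ins), 1L)
  expect_gt(ins$beta_exposure_minutes, 0)
  expect_true(ins$eaf > 0 && ins$eaf < 1)
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_participants = 300, n_snps = 6, seed = 42)
  expect_identical(simulate_instruments(cfg), simulate_instruments(cfg))
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$genotypes, s2$genotypes)

  # byte-identical files on disk
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(s1, d1); write_cohort(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("cohort respects its contracts", {
  out <- make_dataset(sim_config(n_participants = 3000, n_snps = 10,
                                 seed = 7))
  dat <- out$dat
  G <- as.matrix(out$sim$genotypes[out$sim$instruments$snp_id])
  expect_true(all(G %in% 0:2))
  expect_true(all(dat$sleep_hours %in% 4:11))
  prev <- colMeans(dat[c("central_obesity", "high_bp", "dyslipidemia",
                         "hypertriglyceridemia", "hyperglycemia")])
  expect_true(all(prev > 0 & prev < 1))
  # medication flags are only assigned to affected participants, so the
  # flag always coincides with its derived component
  expect_true(all(dat$high_bp[dat$antihypertensive]))
  expect_true(all(dat$hyperglycemia[dat$diabetes_drug]))
})

test_that("null dose-response gives a null GRS-outcome association", {
  cfg <- sim_config(n_participants = 20000,
                    dose_response = dose_response("null"), seed = 11)
  dat <- make_dataset(cfg)$dat
  fit <- grs_outcome_regression(dat, "hypertriglyceridemia",
                                covariates = c("age", "sex"),
                                per_doubling = FALSE)
  expect_lt(abs(fit$beta), 3 * fit$se)
})

test_that("null-truth IVW z-statistics are standard normal across replicates", {
  z <- vapply(1:200, function(i) {
    cfg <- sim_config(n_participants = 4000, n_snps = 15,
                      dose_response = dose_response("null"),
                      seed = 5000 + i)
    out <- make_dataset(cfg)
    dat <- out$dat; sim <- out$sim
    ss <- snp_summary_stats(dat, sim$genotypes, sim$instruments,
                            "hypertriglyceridemia",
                            covariates = c("age", "sex"))
    fit <- mr_ivw(ss)
    fit$beta / fit$se
  }, numeric(1))
  ks <- stats::ks.test(z, "pnorm")
  expect_gt(ks$p.value, 0.01)
})

test_that("ground truth is retrievable and evaluable", {
  sim <- simulate_cohort(sim_config(n_participants = 100, n_snps = 4,
                                    pleiotropy = list(n = 2L, effect = 0.1,
                                                      balanced = TRUE),
                                    seed = 3))
  tr <- sim$truth
  expect_length(tr$beta_hours, 4L)
  expect_equal(tr$pleiotropic_snps, sim$instruments$snp_id[1:2])
  expect_equal(tr$pleiotropic_effects, c(0.1, -0.1))
  expect_no_error(dr_value(tr$dose_response, seq(4, 11, 0.5)))
})

test_that("round-trip through plain-text files preserves the tables", {
  sim <- simulate_cohort(sim_config(n_participants = 50, n_snps = 3,
                                    seed = 9))
  d <- withr::local_tempdir()
  write_cohort(sim, d)
  back <- read_cohort(d)
  expect_equal(as.data.frame(back$instruments),
               as.data.frame(sim$instruments))
  expect_equal(back$genotypes$participant_id, sim$genotypes$participant_id)
  expect_equal(as.matrix(back$genotypes[-1]),
               as.matrix(sim$genotypes[-1]), ignore_attr = TRUE)
  expect_error(read_cohort(file.path(d, "nope")), "Missing")
})
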