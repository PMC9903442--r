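# Shared fixtures: all synthetic, built in code.

# Simulate a cohort and assemble the analysis tibble in one call.
make_dataset <- function(cfg) {
  sim <- simulate_cohort(cfg)
  list(sim = sim,
       dat = assemble_analysis(sim$cohort, sim$genotypes, sim$instruments))
}

# A small hand-buildable summary-statistics tibble.
make_ss <- function(beta_gx, beta_gy, se_gy, se_gx = rep(1e-6, length(beta_gx))) {
  tibble::tibble(
    snp_id = sprintf("snp_%d", seq_along(beta_gx)),
    beta_gx = beta_gx, se_gx = se_gx,
    beta_gy = beta_gy, se_gy = se_gy, n = 1000L
  )
}

# One complete biomarker record with every component below its cutoff;
# fields can be overridden per test.
base_record <- function(...) {
  rec <- tibble::tibble(
    sex = "male", waist_cm = 90, sbp_1 = 120, sbp_2 = 118,
    dbp_1 = 78, dbp_2 = 76, hdl_mmol = 1.4, tg_mmol = 1.2,
    hba1c_mmol = 38, antihypertensive = FALSE, hdl_drug = FALSE,
    tg_drug = FALSE, diabetes_drug = FALSE
  )
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}
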