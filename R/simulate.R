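#' Configuration for the synthetic biobank cohort generator
#'
#' Bundles every knob of the simulator: cohort size, the additive genetic
#' basis of sleep duration, confounding, the causal dose-response curve,
#' pleiotropy, and component prevalences. Defaults emulate a UK-Biobank-like
#' study population: discrete self-reported sleep of 4-11 h centred near
#' 7.2 h with SD close to 1 h, a 78-SNP additive basis explaining 0.62% of
#' sleep variance, and component prevalences near those observed in the
#' 7-8 h sleep stratum of such cohorts.
#'
#' @param n_participants cohort size.
#' @param n_snps number of instrument SNPs (default 78).
#' @param target_r2 fraction of sleep-duration variance explained by the
#'   genetic risk score, in `(0, 0.05)` (default 0.0062).
#' @param eaf_range range the effect-allele frequencies are drawn from.
#' @param dose_response a [dose_response()] object; the true causal curve.
#' @param confounders list with `deprivation = c(sleep =, outcome =)` and
#'   `smoking = c(prev =, sleep =, outcome =)`: effects of a continuous
#'   deprivation-like confounder (per SD, hours / log-odds) and a binary
#'   smoking-like confounder. Both confound sleep and all outcomes and are
#'   deliberately *not* emitted as adjustable covariates.
#' @param age_effects `c(sleep =, outcome =)`: effect of age (per year,
#'   centred) on sleep and outcome log-odds; age is an observed covariate.
#' @param sex_outcome_effect log-odds shift for males on each outcome.
#' @param pleiotropy list `list(n =, effect =, balanced =)`: number of
#'   instrument SNPs given a direct (horizontal-pleiotropic) effect on the
#'   outcomes, the per-allele log-odds effect, and whether signs alternate
#'   (balanced) or are all positive (directional).
#' @param baseline_prevalence named vector of component prevalences at the
#'   reference sleep duration (central_obesity, high_bp, dyslipidemia,
#'   hypertriglyceridemia, hyperglycemia).
#' @param med_rates named vector: probability that a participant with a
#'   component is on the corresponding medication (antihypertensive,
#'   hdl_drug, tg_drug, diabetes_drug).
#' @param mean_sleep mean of the continuous latent sleep duration (hours).
#' @param sd_noise SD of the non-genetic, non-confounder sleep noise.
#' @param reference_sleep hour at which `baseline_prevalence` applies.
#' @param seed integer seed (< 2^30); all randomness is derived from it.
#'
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_instruments()], [simulate_cohort()]
#' @export
sim_config <- function(n_participants = 10000L,
                       n_snps = 78L,
                       target_r2 = 0.0062,
                       eaf_range = c(0.05, 0.95),
                       dose_response = sleepmr::dose_response("l_shaped"),
                       confounders = list(
                         deprivation = c(sleep = -0.1, outcome = 0.15),
                         smoking = c(prev = 0.1, sleep = -0.2, outcome = 0.3)
                       ),
                       age_effects = c(sleep = 0.01, outcome = 0.03),
                       sex_outcome_effect = 0.2,
                       pleiotropy = list(n = 0L, effect = 0.15,
                                         balanced = FALSE),
                       baseline_prevalence = c(
                         central_obesity = 0.33, high_bp = 0.65,
                         dyslipidemia = 0.20, hypertriglyceridemia = 0.48,
                         hyperglycemia = 0.08
                       ),
                       med_rates = c(antihypertensive = 0.3, hdl_drug = 0.1,
                                     tg_drug = 0.1, diabetes_drug = 0.3),
                       mean_sleep = 7.2,
                       sd_noise = 1.0,
                       reference_sleep = 7,
                       seed = 1L) {
  bad <- function(field, msg) {
    abort(sprintf("Invalid `%s`: %s", field, msg), class = "sleepmr_config_error")
  }
  if (!is.numeric(n_participants) || n_participants < 1) {
    bad("n_participants", "must be a positive integer")
  }
  if (!is.numeric(n_snps) || n_snps < 1) bad("n_snps", "must be >= 1")
  if (!is.numeric(target_r2) || target_r2 <= 0 || target_r2 >= 0.05) {
    bad("target_r2", "must lie in (0, 0.05)")
  }
  if (length(eaf_range) != 2L || any(eaf_range <= 0) || any(eaf_range >= 1) ||
      eaf_range[1] > eaf_range[2]) {
    bad("eaf_range", "must be an increasing pair in (0, 1)")
  }
  if (!inherits(dose_response, "dose_response")) {
    bad("dose_response", "must be a dose_response() object")
  }
  comp_names <- c("central_obesity", "high_bp", "dyslipidemia",
                  "hypertriglyceridemia", "hyperglycemia")
  if (!all(comp_names %in% names(baseline_prevalence))) {
    bad("baseline_prevalence", paste("must name all of:",
                                     paste(comp_names, collapse = ", ")))
  }
  if (any(baseline_prevalence <= 0) || any(baseline_prevalence >= 1)) {
    bad("baseline_prevalence", "prevalences must lie in (0, 1)")
  }
  if (!is.numeric(seed) || length(seed) != 1L || abs(seed) >= 2^30) {
    bad("seed", "must be a single integer with |seed| < 2^30")
  }
  if (!is.numeric(sd_noise) || sd_noise <= 0) bad("sd_noise", "must be > 0")
  if (pleiotropy$n > n_snps) bad("pleiotropy", "n must be <= n_snps")

  structure(
    list(
      n_participants = as.integer(n_participants),
      n_snps = as.integer(n_snps),
      target_r2 = target_r2,
      eaf_range = eaf_range,
      dose_response = dose_response,
      confounders = confounders,
      age_effects = age_effects,
      sex_outcome_effect = sex_outcome_effect,
      pleiotropy = pleiotropy,
      baseline_prevalence = baseline_prevalence[comp_names],
      med_rates = med_rates,
      mean_sleep = mean_sleep,
      sd_noise = sd_noise,
      reference_sleep = reference_sleep,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Expected non-genetic variance of the rounded sleep variable implied by
# a config. Rounding to whole hours adds ~1/12 (uniform rounding error);
# truncation at 4/11 is > 3.5 SD out and is ignored.
sim_sleep_nongenetic_var <- function(config) {
  cf <- config$confounders
  cf$deprivation[["sleep"]]^2 +
    cf$smoking[["prev"]] * (1 - cf$smoking[["prev"]]) * cf$smoking[["sleep"]]^2 +
    config$age_effects[["sleep"]]^2 * 64 +  # age SD 8 years
    config$sd_noise^2 + 1 / 12
}

#' Simulate a per-SNP instrument table for sleep duration
#'
#' Draws effect-allele frequencies uniformly in `eaf_range` and per-SNP
#' effects on sleep duration (reported in minutes per effect allele, as in
#' GWAS instrument tables), scaled so that the implied unweighted genetic
#' risk score explains `target_r2` of the sleep variance in expectation.
#' Effects are oriented to the sleep-increasing allele, so all betas are
#' positive. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @return A tibble with columns `snp_id`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta_exposure_minutes`, `se`, `pval`.
#' @examples
#' ins <- simulate_instruments(sim_config(n_snps = 5, seed = 7))
#' ins
#' @export
simulate_instruments <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_snps
  eaf <- runif(m, config$eaf_range[1], config$eaf_range[2])
  raw <- abs(rnorm(m)) + 0.2          # relative effect magnitudes
  # Scale effects so the *unweighted* allele count explains target_r2 of
  # the sleep variance:
  #   R2 = (sum(beta * v))^2 / (sum(v) * var_sleep), v = 2 eaf (1 - eaf),
  # with var_sleep = nongenetic + sum(beta^2 * v) solved jointly.
  v <- 2 * eaf * (1 - eaf)
  r2 <- config$target_r2
  A <- sum(raw * v)
  B <- sum(raw^2 * v)
  s2 <- r2 * sum(v) * sim_sleep_nongenetic_var(config) /
    (A^2 - r2 * sum(v) * B)
  if (s2 <= 0) abort("target_r2 unattainable for the drawn effect spectrum.")
  beta_h <- raw * sqrt(s2)            # hours per allele
  zstat <- runif(m, 6, 15)            # genome-wide significant associations
  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, m, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1L), character(1))
  tibble(
    snp_id = sprintf("rs%07d", sample.int(9999999L, m)),
    effect_allele = ea,
    other_allele = unname(oa),
    eaf = eaf,
    beta_exposure_minutes = beta_h * 60,
    se = beta_h * 60 / zstat,
    pval = 2 * pnorm(-zstat)
  )
}

# Draw a biomarker value on the given side of a cutoff.
# affected = TRUE puts the value at or beyond the cutoff in direction `dir`
# (+1: high values abnormal, -1: low values abnormal).
biomarker_side <- function(affected, cutoff, dir, spread_in, spread_out,
                           margin, floor = 0) {
  n <- length(affected)
  off <- numeric(n)
  off[affected] <- (abs(rnorm(sum(affected), 0, spread_in)) + margin)
  off[!affected] <- -(abs(rnorm(sum(!affected), 0, spread_out)) + margin)
  pmax(floor, cutoff + dir * off)
}

#' Simulate a biobank-style cohort with known causal ground truth
#'
#' Generates genotype dosages (independent binomial(2, EAF) per SNP),
#' discrete sleep duration built from the additive genetic score plus
#' confounders and noise (rounded to whole hours, truncated to 4-11),
#' and raw biomarkers whose derived binary components follow
#' `logit P(component) = intercept + g(sleep) + confounders + pleiotropy`,
#' where `g` is the configured [dose_response()] curve. Biomarkers are
#' drawn on the appropriate side of each diagnostic cutoff so that the
#' rules in [derive_components()] — not pre-made flags — reproduce the
#' latent component indicators; medication flags are assigned only among
#' affected participants and dominate the biomarker where applicable.
#'
#' @param config a [sim_config()] object.
#' @param instruments optional instrument tibble from
#'   [simulate_instruments()]; simulated from `config` when omitted. Must
#'   have `config$n_snps` rows.
#' @return A list of class `sleepmr_sim` with elements:
#'   * `cohort`: tibble of participant covariates, sleep and biomarkers;
#'   * `genotypes`: tibble `participant_id` + one dosage column per SNP;
#'   * `instruments`: the instrument table used;
#'   * `truth`: `sleepmr_truth` object (per-SNP true effects in hours,
#'     the dose-response curve, confounder coefficients, pleiotropic SNP
#'     ids and effects, reference sleep).
#' @examples
#' sim <- simulate_cohort(sim_config(n_participants = 500, n_snps = 5))
#' dplyr::glimpse(sim$cohort)
#' @export
simulate_cohort <- function(config, instruments = NULL) {
  stopifnot(inherits(config, "sim_config"))
  instruments <- instruments %||% simulate_instruments(config)
  if (nrow(instruments) != config$n_snps) {
    abort("`instruments` must have `config$n_snps` rows.")
  }
  set.seed(config$seed + 1L)
  n <- config$n_participants
  m <- config$n_snps
  beta_h <- instruments$beta_exposure_minutes / 60

  G <- matrix(rbinom(n * m, 2L, rep(instruments$eaf, each = n)), n, m)
  colnames(G) <- instruments$snp_id

  age <- pmin(69, pmax(40, rnorm(n, 56.9, 8)))
  sex <- ifelse(runif(n) < 0.462, "male", "female")
  centre <- sample.int(22L, n, replace = TRUE)
  array <- rbinom(n, 1L, 0.9)
  pcs <- matrix(rnorm(n * 10L), n, 10L,
                dimnames = list(NULL, paste0("pc", 1:10)))
  deprivation <- rnorm(n)
  cf <- config$confounders
  smoking <- rbinom(n, 1L, cf$smoking[["prev"]])

  genetic <- as.numeric(G %*% beta_h) - sum(2 * instruments$eaf * beta_h)
  sleep_cont <- config$mean_sleep + genetic +
    cf$deprivation[["sleep"]] * deprivation +
    cf$smoking[["sleep"]] * smoking +
    config$age_effects[["sleep"]] * (age - 56.9) +
    rnorm(n, 0, config$sd_noise)
  sleep_hours <- pmin(11L, pmax(4L, as.integer(round(sleep_cont))))

  # pleiotropic direct effects on the outcome logit (centred dosages)
  n_pleio <- config$pleiotropy$n
  pleio_ids <- character(0)
  pleio_eff <- numeric(0)
  pleio_term <- 0
  if (n_pleio > 0) {
    idx <- seq_len(n_pleio)
    pleio_ids <- instruments$snp_id[idx]
    pleio_eff <- rep(config$pleiotropy$effect, n_pleio)
    if (isTRUE(config$pleiotropy$balanced)) {
      pleio_eff <- pleio_eff * rep_len(c(1, -1), n_pleio)
    }
    Gc <- sweep(G[, idx, drop = FALSE], 2, 2 * instruments$eaf[idx])
    pleio_term <- as.numeric(Gc %*% pleio_eff)
  }

  dr <- config$dose_response
  g_term <- dr_value(dr, sleep_hours) - dr_value(dr, config$reference_sleep)
  shared <- g_term +
    cf$deprivation[["outcome"]] * deprivation +
    cf$smoking[["outcome"]] * smoking +
    config$age_effects[["outcome"]] * (age - 56.9) +
    config$sex_outcome_effect * (sex == "male") +
    pleio_term

  prev <- config$baseline_prevalence
  z <- lapply(prev, function(p0) {
    rbinom(n, 1L, plogis(qlogis(p0) + shared)) == 1L
  })

  med <- config$med_rates
  female <- sex == "female"

  # central obesity: waist vs sex-specific cutoff (88 cm women, 102 cm men)
  waist_cut <- ifelse(female, 88, 102)
  waist <- biomarker_side(z$central_obesity, waist_cut, +1, 8, 10, 0.5, 55)

  # high blood pressure: both SBP >= 130 or both DBP >= 85 or medication
  on_ah <- z$high_bp & runif(n) < med[["antihypertensive"]]
  raised <- z$high_bp & !on_ah
  sbp1 <- ifelse(raised, 130 + abs(rnorm(n, 0, 15)) + 0.5,
                 130 - abs(rnorm(n, 0, 12)) - 0.5)
  sbp2 <- ifelse(raised, 130 + abs(rnorm(n, 0, 15)) + 0.5, rnorm(n, 124, 12))
  dbp1 <- ifelse(raised, rnorm(n, 82, 8), 85 - abs(rnorm(n, 0, 8)) - 0.5)
  dbp2 <- rnorm(n, 79, 8)

  # dyslipidemia: low HDL (< 1.0 male, < 1.3 female) or HDL drug
  hdl_cut <- ifelse(female, 1.3, 1.0)
  on_hdl <- z$dyslipidemia & runif(n) < med[["hdl_drug"]]
  low_hdl <- z$dyslipidemia & !on_hdl
  hdl <- ifelse(low_hdl,
                pmax(0.3, hdl_cut - abs(rnorm(n, 0, 0.25)) - 0.02),
                hdl_cut + abs(rnorm(n, 0, 0.35)) + 0.02)

  # hypertriglyceridemia: TG >= 1.7 or TG-lowering drug
  on_tg <- z$hypertriglyceridemia & runif(n) < med[["tg_drug"]]
  high_tg <- z$hypertriglyceridemia & !on_tg
  tg <- ifelse(high_tg, 1.7 + abs(rnorm(n, 0, 1.0)) + 0.02,
               pmax(0.2, 1.7 - abs(rnorm(n, 0, 0.6)) - 0.02))

  # hyperglycemia: HbA1c >= 42 mmol/mol or diabetes medication
  on_dm <- z$hyperglycemia & runif(n) < med[["diabetes_drug"]]
  high_a1c <- z$hyperglycemia & !on_dm
  hba1c <- ifelse(high_a1c, 42 + abs(rnorm(n, 0, 6)) + 0.2,
                  pmax(20, 42 - abs(rnorm(n, 0, 4)) - 0.2))

  cohort <- tibble(
    participant_id = seq_len(n),
    age = age, sex = sex, centre = centre, array = array,
    as_tibble(pcs),
    deprivation = deprivation, smoking = smoking,
    sleep_hours = sleep_hours,
    waist_cm = waist,
    sbp_1 = sbp1, sbp_2 = sbp2, dbp_1 = dbp1, dbp_2 = dbp2,
    hdl_mmol = hdl, tg_mmol = tg, hba1c_mmol = hba1c,
    antihypertensive = on_ah, hdl_drug = on_hdl,
    tg_drug = on_tg, diabetes_drug = on_dm
  )
  genotypes <- tibble(participant_id = seq_len(n), as_tibble(G))
  truth <- structure(
    list(
      snp_id = instruments$snp_id,
      beta_hours = beta_h,
      eaf = instruments$eaf,
      dose_response = dr,
      confounders = cf,
      age_effects = config$age_effects,
      sex_outcome_effect = config$sex_outcome_effect,
      pleiotropic_snps = pleio_ids,
      pleiotropic_effects = pleio_eff,
      baseline_prevalence = prev,
      reference_sleep = config$reference_sleep
    ),
    class = "sleepmr_truth"
  )
  structure(
    list(cohort = cohort, genotypes = genotypes,
         instruments = instruments, truth = truth, config = config),
    class = "sleepmr_sim"
  )
}

#' @export
print.sleepmr_sim <- function(x, ...) {
  cat(sprintf(
    "<sleepmr_sim> %d participants, %d SNPs, dose-response '%s'\n",
    nrow(x$cohort), nrow(x$instruments), x$truth$dose_response$shape))
  invisible(x)
}

#' Write a simulated cohort to plain-text files
#'
#' Writes the genotype dosage matrix as TSV (rows = participants, one
#' column per SNP id), the phenotype table as CSV, the instrument table as
#' TSV, and the ground truth as JSON, into `dir`.
#'
#' @param sim a `sleepmr_sim` object from [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written (named character vector).
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "sleepmr_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    genotypes = file.path(dir, "genotypes.tsv"),
    phenotypes = file.path(dir, "phenotypes.csv"),
    instruments = file.path(dir, "instruments.tsv"),
    truth = file.path(dir, "ground_truth.json")
  )
  readr::write_tsv(sim$genotypes, paths[["genotypes"]])
  readr::write_csv(sim$cohort, paths[["phenotypes"]])
  readr::write_tsv(sim$instruments, paths[["instruments"]])
  tr <- sim$truth
  jsonlite::write_json(
    list(
      snp_id = tr$snp_id, beta_hours = tr$beta_hours, eaf = tr$eaf,
      dose_response = unclass(tr$dose_response),
      confounders = tr$confounders,
      pleiotropic_snps = tr$pleiotropic_snps,
      pleiotropic_effects = tr$pleiotropic_effects,
      baseline_prevalence = as.list(tr$baseline_prevalence),
      reference_sleep = tr$reference_sleep
    ),
    paths[["truth"]], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param dir directory containing `genotypes.tsv`, `phenotypes.csv` and
#'   `instruments.tsv`.
#' @return A list with `cohort`, `genotypes`, `instruments` tibbles.
#' @export
read_cohort <- function(dir) {
  need <- c("genotypes.tsv", "phenotypes.csv", "instruments.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    abort(paste0("Missing cohort file(s) in ", dir, ": ",
                 paste(missing, collapse = ", ")))
  }
  list(
    cohort = readr::read_csv(file.path(dir, "phenotypes.csv"),
                             show_col_types = FALSE),
    genotypes = readr::read_tsv(file.path(dir, "genotypes.tsv"),
                                show_col_types = FALSE),
    instruments = readr::read_tsv(file.path(dir, "instruments.tsv"),
                                  show_col_types = FALSE)
  )
}
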