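# sleepmr

One-sample linear and nonlinear Mendelian randomization (MR) for the
causal effect of habitual sleep duration on metabolic syndrome (MetS)
and its five components, with a synthetic biobank-style cohort
generator that has a known causal ground truth.

## Who this is for

Epidemiologists and statistical geneticists who want a tested,
scriptable implementation of the one-sample MR workflow for a discrete
exposure (self-reported sleep in whole hours, 4–11 h) and binary
metabolic outcomes derived from raw biomarkers — and who need to
validate every estimator against an oracle before trusting it on
restricted individual-level data.

## What it computes

* **Phenotype derivation** — sleep cleaning (4–11 h kept, non-response
  and out-of-range excluded with reasons) and the five MetS components
  from biomarkers and medication flags: waist ≥ 88/102 cm
  (women/men); both SBP readings ≥ 130 or both DBP ≥ 85 mmHg or
  antihypertensives; HDL < 1.0/1.3 mmol/L or HDL drugs;
  triglycerides ≥ 1.7 mmol/L or TG drugs; HbA1c ≥ 42 mmol/mol or
  diabetes drugs. MetS = ≥ 3 components.
* **Genetic risk scores** — unweighted (count of sleep-increasing
  alleles, negative-effect SNPs re-oriented) and weighted scores;
  instrument strength as incremental R² and partial F
  (univariate identity `F = (n−2)R²/(1−R²)`); a GRS–confounder screen
  at a Bonferroni threshold (default 0.004).
* **Linear MR** — two-stage predictor substitution (OLS first stage,
  logistic second stage on fitted exposure; log OR per hour), per-SNP
  summary statistics, IVW with multiplicative random-effects SE
  inflation, weighted median (bootstrap SE), MR-Egger (pleiotropy
  intercept), radial MR with modified second-order weights and
  outlier flagging at 0.05/J, rescaling between per-minute/per-hour
  (×60) and per-doubling (×0.693) scales, and Monte-Carlo power.
* **Nonlinear MR** — k equal-count strata of the IV-free exposure
  residual, a localized average causal effect (LACE) per stratum, the
  quadratic trend test and Cochran's Q across strata, and a continuous
  piecewise-linear causal curve anchored at a reference exposure.
* **Synthetic cohorts** — `sim_config()` / `simulate_cohort()` generate
  genotypes, covariates, confounders, discrete sleep and raw biomarkers
  under a configurable dose-response (linear, L-shaped, U-shaped, null),
  with the generating truth retrievable via `true_lace()`.

Everything is data-frame-first and pipe-friendly; fitted objects have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Simulate a 50,000-participant cohort under the default L-shaped truth
(log-odds slope −0.3 per hour below 7 h, flat above; 78 SNPs explaining
0.62% of sleep variance), then estimate:

```r
library(sleepmr)

sim <- simulate_cohort(sim_config(n_participants = 50000, seed = 42))
dat <- assemble_analysis(sim$cohort, sim$genotypes, sim$instruments)

instrument_strength(dat, covariates = c("age", "sex"))
#>        r2 f_stat     n n_covariates
#> 1 0.00644   324. 50000            2

mr_two_stage(dat, "hypertriglyceridemia", covariates = c("age", "sex"))
#> <mr_fit: two_stage> scale = per_hour
#>   log-OR -0.0977 (SE 0.107), 95% CI [-0.308, 0.112], p = 0.361
#>   OR 0.907 [0.735, 1.12]

nl <- mr_nonlinear(dat, "hypertriglyceridemia", covariates = c("age", "sex"))
tidy(nl)[, c("stratum", "n", "exposure_mean", "beta", "se", "p")]
#>   stratum     n exposure_mean    beta     se        p
#> 1       1 16667          6.09 -0.241  0.0716 0.000746
#> 2       2 16667          7.14 -0.0619 0.0875 0.479
#> 3       3 16666          8.33 -0.0738 0.184  0.689

true_lace(sim$truth, c(4, 7, 11))
#> [1] -0.3  0.0
```

Read: the instrument explains 0.64% of sleep variance (F = 324). The
*linear* two-stage estimate per hour is null (OR 0.91, p = 0.36) —
exactly the attenuation a linear model suffers under an L-shaped truth —
while the stratified analysis recovers the short-sleep effect
(lowest-stratum LACE −0.24 log-odds/h, p = 7×10⁻⁴, truth −0.3) and a
null effect in the longer-sleep strata (truth 0). `autoplot(nl)` draws
the piecewise causal curve with its confidence band.

The full pipeline (cleaning → components → GRS → linear + nonlinear MR
→ report tables) runs from one config:

```r
report <- run_pipeline(pipeline_config(
  sim = sim_config(n_participants = 50000, seed = 42),
  covariates = c("age", "sex")
))
report$estimates          # per outcome x method, OR with CI and p
write_report(report, "out/")   # TSV/CSV/JSON artifacts
```

A thin CLI over the same functions lives in `inst/scripts/sleepmr`
(subcommands `simulate`, `derive`, `grs`, `mr-linear`, `mr-nonlinear`,
`report`, `run-all`; YAML config).

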