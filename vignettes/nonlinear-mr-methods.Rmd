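---
title: "Linear and nonlinear Mendelian randomization for sleep duration and metabolic syndrome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear and nonlinear Mendelian randomization for sleep duration and metabolic syndrome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepmr)
library(dplyr)
```

## The scientific problem

Observational studies repeatedly associate both short and long habitual
sleep with metabolic syndrome (MetS), but such associations are
vulnerable to confounding and reverse causation. Mendelian randomization
(MR) uses genetic variants as instrumental variables: because alleles
are fixed at conception, a genetic score that shifts sleep duration can
identify the causal effect of sleep on metabolic outcomes, provided the
variants affect the outcome only through sleep.

`sleepmr` implements the one-sample version of this design for a
biobank-style cohort: individual-level genotype dosages, self-reported
sleep duration in whole hours (4–11 h after cleaning), and raw
biomarkers from which MetS and its five components — central obesity,
high blood pressure, dyslipidemia, hypertriglyceridemia, hyperglycemia —
are derived by standard cutoffs. Because real biobank data cannot be
redistributed, the package ships a synthetic-cohort generator with a
known causal ground truth, so every estimator can be validated against
an oracle.

## The estimators

**Two-stage predictor substitution.** Stage one regresses sleep hours
$X$ on the unweighted genetic risk score $S$ (a count of
sleep-increasing alleles) plus covariates $C$ by OLS; stage two is a
logistic regression of the binary outcome on the stage-one fitted values
$\hat X$ plus the same covariates. The coefficient of $\hat X$ is the
causal log odds ratio per hour of genetically predicted sleep. We report
conventional model-based standard errors from stage two; the uncertainty
in $\hat X$ is not propagated. With an instrument this strong
(F of a few hundred at the cohort sizes used here) the omitted term is
small, and the Monte-Carlo coverage checks in the test suite confirm the
nominal 95% interval covers a planted slope at close to its nominal
rate.

**Summary-statistic estimators.** Per-SNP associations
$(\hat\beta_{GX,j}, \hat\beta_{GY,j})$ are estimated inside the same
cohort (linear for exposure, logistic for outcome). From these:

* IVW: $\hat\beta = \sum_j w_j \hat r_j / \sum_j w_j$ with Wald ratios
  $\hat r_j = \hat\beta_{GY,j}/\hat\beta_{GX,j}$ and first-order weights
  $w_j = \hat\beta_{GX,j}^2/\mathrm{se}(\hat\beta_{GY,j})^2$. The SE is
  inflated by $\max(1, \sqrt{Q/(J-1)})$ — a multiplicative
  random-effects model, the standard conservative choice when
  heterogeneity is present.
* Weighted median: the 50% point of the inverse-variance-weighted
  cumulative distribution of ratios (midpoint interpolation), with a
  parametric-bootstrap SE under a mandatory seed.
* MR-Egger: weighted regression of $\hat\beta_{GY}$ on
  $\hat\beta_{GX}$ with a free intercept after orienting all SNPs to
  positive exposure effects; the intercept estimates directional
  pleiotropy. Dispersion is floored at one and inference uses a t
  reference with $J-2$ degrees of freedom.
* Radial MR: the IVW estimate re-expressed as a regression through the
  origin of $\hat r_j\sqrt{w_j}$ on $\sqrt{w_j}$ with *modified
  second-order weights*
  $w_j = \hat\beta_{GX,j}^2 / (\mathrm{se}_{GY,j}^2 +
  \hat\beta^2\,\mathrm{se}_{GX,j}^2)$, iterated from the first-order IVW
  value until the slope changes by less than $10^{-8}$ (at most 100
  iterations). Each SNP's contribution to Cochran's Q is referred to
  $\chi^2_1$; SNPs below $\alpha = 0.05/J$ are flagged as outliers, and
  the pipeline removes them and re-estimates once (no recursive
  re-screening).

**Nonlinear MR by residual stratification.** The sample is split into
$k$ equal-count strata of the *IV-free exposure* — the residual of
sleep after regressing out the score (and, by default, the covariates;
a score-only residual is available via `residual_covariates = FALSE`).
Within each stratum the two-stage estimator gives a localized average
causal effect (LACE), the gradient of one segment of a piecewise-linear
causal curve that is continuous by construction. Nonlinearity is tested
two ways: a fixed-effect meta-regression of the LACEs on the stratum
exposure positions (the quadratic test, Wald p with a normal
reference) and Cochran's Q across strata. The default $k = 3$ reflects
that an exposure recorded in whole hours supports only a few distinct
strata; $k$ is a parameter.

Two genuinely open choices are settled as follows. The x-position of a
stratum in the quadratic test is its observed mean exposure (a
`midpoint` option exists); and the curve's segment boundaries default to
the overall exposure range split at midpoints between consecutive
stratum exposure means, because residual strata overlap in raw exposure
and have no sharp natural boundaries. The curve is anchored at zero at a
reference exposure (default 7 h). The "L-shaped"/"U-shaped" label the
package prints is a description of the sign pattern of the LACEs, not a
test statistic.

## Reporting scales

Stage-one effects are in hours, so causal estimates are log odds ratios
per hour; estimates produced per minute are rescaled by 60. For binary
sleep traits instrumented by a weighted liability score, the direct
score-outcome logistic coefficient is multiplied by $\log 2 = 0.693$ and
reported per doubling of genetic liability. Rescaling multiplies the
point estimate and SE and leaves the p-value unchanged. Main-analysis
significance uses a Bonferroni threshold of $0.05/6 = 0.008$ across the
six outcomes; the confounder screen uses $0.004$ and radial outlier
flagging $0.05/J$, all configurable.

## What the synthetic cohort emulates — and what it does not

The generator (`sim_config()`, `simulate_instruments()`,
`simulate_cohort()`) emulates the features of the study population that
matter to the estimators:

* discrete sleep of 4–11 h, built as a continuous latent variable
  (mean 7.2 h, total SD close to 1 h) that is rounded and truncated —
  the rounding contributes $1/12$ to the variance bookkeeping and
  truncation beyond ±3.5 SD is ignored;
* an additive basis of 78 independent SNPs whose effects are scaled so
  the *unweighted* allele count explains 0.62% of sleep variance in
  expectation (the weighted score explains slightly more; the unweighted
  count is what the design instruments on, so that is what is
  calibrated). Effect-allele frequencies are uniform on (0.05, 0.95), a
  free choice documented as such;
* shared confounders of sleep and outcome that are deliberately *not*
  exposed as adjustable covariates (a continuous deprivation-like and a
  binary smoking-like confounder), plus observed covariates (age, sex)
  that are;
* binary components generated from a configurable piecewise-linear
  dose-response on the log-odds scale (linear, L-shaped, U-shaped,
  null), with baseline prevalences near the normal-sleep stratum of a
  European biobank cohort (central obesity 0.33, high blood pressure
  0.65, dyslipidemia 0.20, hypertriglyceridemia 0.48, hyperglycemia
  0.08);
* biomarkers drawn on the correct side of each diagnostic cutoff given
  the latent component state, so the derivation rules — not pre-made
  flags — produce the outcomes, and medication flags assigned only among
  affected participants (treatment rates 0.3/0.1/0.1/0.3) so that
  flag-dominance never contradicts the generating model;
* optional pleiotropic SNPs acting additively on the outcome logit,
  directional by default, balanced (alternating signs) on request.

It does **not** simulate linkage disequilibrium, imputation uncertainty,
relatedness, assortative mating, or selection into the cohort. Passing
tests therefore demonstrate that the estimators do what they claim under
an idealized independent-SNP data-generating process — not that the
substantive findings would survive those real-data complications.

```{r curve-example, fig.width = 5, fig.height = 3.5}
cfg <- sim_config(n_participants = 20000, seed = 42)
sim <- simulate_cohort(cfg)
dat <- assemble_analysis(sim$cohort, sim$genotypes, sim$instruments)
fit <- mr_nonlinear(dat, "hypertriglyceridemia",
                    covariates = c("age", "sex"))
glance(fit)
autoplot(fit)
```

The generating curve here is the default L-shape (slope −0.3 log-odds
per hour below 7 h, flat above); `true_lace()` evaluates the oracle
slopes for any stratum boundaries. Note that the configured
dose-response applies to each *component*; MetS, being "three or more
components", inherits a steeper compound curve whose exact slope has no
closed form — so oracle-based recovery checks target the components,
while MetS results are interpreted qualitatively.

## Numerical choices and degenerate inputs

* All regressions in simulation-heavy paths run on pre-built model
  matrices through `lm.fit`/`glm.fit`; logistic fits that fail to
  converge or produce fitted probabilities at machine bounds raise an
  error naming possible separation rather than returning garbage.
* The unweighted score re-orients negative-effect SNPs by
  `dosage -> 2 - dosage` so "number of sleep-increasing alleles" is
  well defined; re-orienting twice restores the input.
* Equal-count stratification breaks ties by stable input order, making
  assignments deterministic and shift-invariant; strata with fewer than
  two distinct exposure values or only one outcome class are rejected
  with the stratum named.
* The weighted-median bootstrap requires an explicit seed; every other
  stochastic step derives from the single simulation seed, and a
  pipeline run is reproducible to identical output given its config.
* Monte-Carlo checks in the test suite use cohorts of 10,000–335,727
  participants and 100–200 replicates per property — sizes chosen so
  each operating characteristic (coverage, test size, detection rate)
  is measured with a Monte-Carlo SE of a few percent.

## Known limitations

* Stage-two SEs ignore first-stage uncertainty (standard practice for
  strong instruments; a bootstrap would be needed near the weak-
  instrument regime).
* The per-doubling rescaling assumes the liability score's units are
  log-odds of the binary sleep trait; scores built from other units
  need rescaling before interpretation.
* The quadratic test inherits the usual caveat of meta-regression on
  few strata: with the default $k = 3$ it has one degree of freedom and
  modest power against shapes whose curvature cancels across strata.
* MetS status with partially missing components is set to `NA` only
  when the missing components could change the ≥3 decision; this keeps
  participants with decided status in the analysis but is one of
  several defensible conventions.
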