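Package: sleepmr
Title: One-Sample Linear and Nonlinear Mendelian Randomization for Sleep
    Duration and Metabolic Syndrome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A one-sample Mendelian randomization (MR) pipeline for the
    causal effect of habitual sleep duration on metabolic syndrome and its
    five components. Builds unweighted and weighted genetic risk scores
    from instrument tables, estimates causal log odds ratios by two-stage
    predictor substitution and by summary-statistic estimators (inverse
    variance weighted, weighted median, MR-Egger) with radial-MR outlier
    screening, and fits piecewise-linear nonlinear MR by residual
    stratification with localized average causal effects (LACE) plus
    quadratic and Cochran Q nonlinearity tests. Includes a synthetic
    biobank-style cohort generator with known ground-truth dose-response
    curves so every estimator can be validated against an oracle, and a
    metabolic-syndrome component deriver implementing standard biomarker
    and medication cutoffs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
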