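#' Pipeline configuration
#'
#' Collects everything [run_pipeline()] needs: either a [sim_config()] to
#' simulate a cohort or paths to genotype/phenotype/instrument files,
#' plus covariates, outcomes, significance levels and reporting options.
#'
#' @param sim a [sim_config()], or `NULL` when reading from files.
#' @param paths named list with `genotypes`, `phenotypes`, `instruments`
#'   file paths (used when `sim` is `NULL`).
#' @param covariates covariate columns for all regression stages.
#' @param outcomes outcomes to analyse (subset of the five components
#'   plus `mets`).
#' @param n_groups number of GRS groups for the group-association table.
#' @param k number of nonlinear-MR strata.
#' @param alpha_main main-analysis significance level; default Bonferroni
#'   `0.05 / length(outcomes)`.
#' @param alpha_screen confounder-screen threshold (default 0.004).
#' @param alpha_radial per-SNP radial outlier level; default `0.05 / J`.
#' @param reference_sleep curve anchor for nonlinear MR (hours).
#' @param filter optional quoted expression (string) applied as a row
#'   filter to the cohort before analysis — used for sensitivity analyses
#'   such as excluding night-shift-like subgroups.
#' @param seed seed controlling the weighted-median bootstrap (and the
#'   simulation when `sim` carries no seed of its own).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, paths = NULL,
                            covariates = c("age", "sex"),
                            outcomes = c("mets", "central_obesity",
                                         "high_bp", "dyslipidemia",
                                         "hypertriglyceridemia",
                                         "hyperglycemia"),
                            n_groups = 3L, k = 3L,
                            alpha_main = NULL, alpha_screen = 0.004,
                            alpha_radial = NULL,
                            reference_sleep = 7,
                            filter = NULL,
                            seed = 1L) {
  if (is.null(sim) && is.null(paths)) {
    abort("Provide either `sim` or `paths`.")
  }
  if (length(outcomes) == 0L) abort("`outcomes` must be non-empty.")
  alpha_main <- alpha_main %||% (0.05 / length(outcomes))
  for (a in c(alpha_main, alpha_screen, alpha_radial)) {
    if (!is.null(a) && (a <= 0 || a >= 1)) {
      abort("All alpha levels must lie in (0, 1).")
    }
  }
  structure(
    list(sim = sim, paths = paths, covariates = covariates,
         outcomes = outcomes, n_groups = as.integer(n_groups),
         k = as.integer(k), alpha_main = alpha_main,
         alpha_screen = alpha_screen, alpha_radial = alpha_radial,
         reference_sleep = reference_sleep, filter = filter,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Descriptive table by sleep-duration group
#'
#' Baseline-characteristics summary in long form: per sleep-hour group
#' (7 and 8 h merged, as is conventional for this exposure), the group
#' size, mean and SD of continuous variables, and count and percentage
#' (to one decimal) of binary variables.
#'
#' @param data analysis tibble (needs `sleep_hours` plus the summarised
#'   columns).
#' @param vars columns to summarise; default: a standard covariate and
#'   outcome set intersected with `names(data)`.
#' @return Tibble: `sleep_group`, `group_n`, `variable`, `mean`, `sd`,
#'   `count`, `pct` (continuous rows have `NA` count/pct and vice versa).
#' @export
descriptive_table <- function(data, vars = NULL) {
  vars <- vars %||% intersect(
    c("age", "deprivation", "smoking", "mets", "central_obesity",
      "high_bp", "dyslipidemia", "hypertriglyceridemia", "hyperglycemia"),
    names(data))
  grp <- as.character(data$sleep_hours)
  grp[data$sleep_hours %in% 7:8] <- "7 or 8"
  grp <- factor(grp, levels = c("4", "5", "6", "7 or 8", "9", "10", "11"))
  long <- purrr::map(vars, function(v) {
    x <- data[[v]]
    binary <- is.logical(x) || all(x %in% c(0, 1, NA))
    d <- tibble(sleep_group = grp, value = as.numeric(x))
    d |>
      dplyr::group_by(.data$sleep_group, .drop = FALSE) |>
      dplyr::summarise(
        group_n = dplyr::n(),
        mean = if (binary) NA_real_ else mean(.data$value, na.rm = TRUE),
        sd = if (binary) NA_real_ else sd(.data$value, na.rm = TRUE),
        count = if (binary) sum(.data$value, na.rm = TRUE) else NA_real_,
        pct = if (binary) {
          round(100 * sum(.data$value, na.rm = TRUE) /
                  max(1, sum(!is.na(.data$value))), 1)
        } else NA_real_,
        .groups = "drop"
      ) |>
      dplyr::mutate(variable = v, .after = "group_n")
  })
  dplyr::bind_rows(long)
}

#' GRS-group associations with a metabolic outcome
#'
#' Splits the score into `n_groups` equal-count groups (lowest group as
#' reference), fits a logistic regression with group indicators plus
#' covariates, and obtains a trend p-value from a second fit with the
#' group index as a single ordinal term.
#'
#' @inheritParams mr_two_stage
#' @param n_groups number of score groups (default 3).
#' @return Tibble with one row per group: `group`, `n`, `or`, `or_low`,
#'   `or_high`, `p` (reference row has OR 1 and `NA` inference), plus
#'   attribute `trend_p`.
#' @export
grs_group_association <- function(data, outcome, score = "grs",
                                  covariates = NULL, n_groups = 3L) {
  if (n_groups < 2L) abort("`n_groups` must be >= 2.")
  s <- data[[score]]
  grp <- dplyr::ntile(s, n_groups)
  if (length(unique(grp)) < n_groups) abort("Empty score group.")
  y <- as.numeric(data[[outcome]])
  X0 <- design_matrix(data, covariates)
  ind <- stats::model.matrix(~ factor(grp))[, -1, drop = FALSE]
  colnames(ind) <- paste0("group", 2:n_groups)
  fit <- fast_logit(cbind(X0, ind), y)
  k0 <- ncol(X0)
  idx <- k0 + seq_len(n_groups - 1L)
  b <- fit$coef[idx]; se <- fit$se[idx]
  b <- unname(b); se <- unname(se)
  out <- tibble(
    group = seq_len(n_groups),
    n = as.integer(table(grp)),
    or = c(1, exp(b)),
    or_low = c(NA, exp(b - 1.96 * se)),
    or_high = c(NA, exp(b + 1.96 * se)),
    p = c(NA, 2 * pnorm(-abs(b / se)))
  )
  trend <- fast_logit(cbind(X0, trend = as.numeric(grp)), y)
  kt <- ncol(X0) + 1L
  attr(out, "trend_p") <-
    2 * pnorm(-abs(trend$coef[[kt]] / trend$se[[kt]]))
  out
}

linear_mr_suite <- function(dat, genotypes, instruments, outcome,
                            covariates, alpha_radial, seed) {
  ts <- mr_two_stage(dat, outcome, covariates = covariates)
  ss <- snp_summary_stats(dat, genotypes, instruments, outcome,
                          covariates = covariates)
  ests <- list(
    two_stage = ts,
    ivw = mr_ivw(ss),
    weighted_median = mr_weighted_median(ss, seed = seed),
    egger = mr_egger(ss)
  )
  rad <- mr_radial(ss, alpha = alpha_radial)
  kept <- ss[!rad$snps$outlier, , drop = FALSE]
  post <- if (nrow(kept) >= 1 && sum(rad$snps$outlier) > 0) {
    mr_ivw(kept)
  } else NULL
  list(estimates = ests, summary_stats = ss, radial = rad,
       ivw_outliers_removed = post)
}

#' Run the full MR pipeline
#'
#' Orchestrates: simulate (or load) -> clean sleep -> derive components
#' -> genetic risk score, strength and confounder screen -> linear MR
#' (two-stage plus IVW / weighted median / MR-Egger with radial outlier
#' exclusion and re-estimation) per outcome -> nonlinear MR per outcome
#' -> descriptive and GRS-group report tables. Deterministic given the
#' config seed.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage-by-stage participant accounting?
#' @return A list of class `sleepmr_report`: `descriptive`, `strength`,
#'   `screen`, `linear` (per outcome), `nonlinear` (per outcome),
#'   `grs_groups` (per outcome), `accounting`, `meta` (seed, config
#'   hash, package version).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  if (!is.null(config$sim)) {
    sim <- simulate_cohort(config$sim)
    cohort <- sim$cohort; genotypes <- sim$genotypes
    instruments <- sim$instruments
  } else {
    p <- config$paths
    for (f in unlist(p)) {
      if (!file.exists(f)) abort(paste0("Input file not found: ", f))
    }
    loaded <- read_cohort(dirname(p$genotypes))
    cohort <- loaded$cohort; genotypes <- loaded$genotypes
    instruments <- loaded$instruments
  }
  accounting <- list(input = nrow(cohort))
  say("input: %d participants", nrow(cohort))

  cleaned <- clean_sleep(cohort$sleep_hours)
  keep <- cleaned$kept
  cohort <- cohort[keep, , drop = FALSE]
  cohort$sleep_hours <- cleaned$hours[keep]
  genotypes <- genotypes[keep, , drop = FALSE]
  accounting$after_sleep_cleaning <- nrow(cohort)
  say("after sleep cleaning: %d", nrow(cohort))

  if (!is.null(config$filter)) {
    keep <- rlang::eval_tidy(rlang::parse_expr(config$filter),
                             data = cohort)
    cohort <- cohort[keep, , drop = FALSE]
    genotypes <- genotypes[keep, , drop = FALSE]
    accounting$after_row_filter <- nrow(cohort)
    say("after row filter: %d", nrow(cohort))
  }

  dat <- assemble_analysis(cohort, genotypes, instruments)
  dat$sleep_category <- categorize_sleep(dat$sleep_hours)

  strength <- instrument_strength(dat, covariates = config$covariates)
  screen_covs <- intersect(c("age", "deprivation", "smoking"), names(dat))
  screen_covs <- screen_covs[vapply(screen_covs,
                                    function(v) sd(as.numeric(dat[[v]])) > 0,
                                    logical(1))]
  screen <- confounder_screen(dat, covariates = screen_covs,
                              alpha = config$alpha_screen)

  linear <- purrr::map(setNames(config$outcomes, config$outcomes),
                       function(oc) {
    say("linear MR: %s", oc)
    linear_mr_suite(dat, genotypes, instruments, oc, config$covariates,
                    config$alpha_radial, seed = config$seed)
  })
  nonlinear <- purrr::map(setNames(config$outcomes, config$outcomes),
                          function(oc) {
    say("nonlinear MR: %s", oc)
    mr_nonlinear(dat, oc, covariates = config$covariates, k = config$k,
                 reference = config$reference_sleep)
  })
  grs_groups <- purrr::map(setNames(config$outcomes, config$outcomes),
                           function(oc) {
    grs_group_association(dat, oc, covariates = config$covariates,
                          n_groups = config$n_groups)
  })

  estimates <- purrr::map_dfr(names(linear), function(oc) {
    dplyr::bind_rows(purrr::map(linear[[oc]]$estimates, glance)) |>
      dplyr::mutate(outcome = oc,
                    significant = .data$p.value < config$alpha_main)
  })

  structure(
    list(
      descriptive = descriptive_table(dat),
      strength = strength,
      screen = screen,
      linear = linear,
      estimates = estimates,
      nonlinear = nonlinear,
      grs_groups = grs_groups,
      accounting = accounting,
      meta = list(seed = config$seed,
                  alpha_main = config$alpha_main,
                  config_hash = rlang::hash(config),
                  package_version =
                    as.character(utils::packageVersion("sleepmr")))
    ),
    class = "sleepmr_report"
  )
}

#' @export
print.sleepmr_report <- function(x, ...) {
  cat("<sleepmr_report>\n")
  cat(sprintf("  participants analysed: %d\n",
              x$accounting[[length(x$accounting)]]))
  cat(sprintf("  GRS strength: R2 = %.4g, F = %.4g\n",
              x$strength$r2, x$strength$f_stat))
  cat("  linear MR estimates:\n")
  print(x$estimates)
  invisible(x)
}

#' Write a report bundle to plain-text files
#'
#' Emits per-outcome estimate tables (TSV), the stratum and curve tables
#' for nonlinear MR (TSV/CSV), the descriptive and GRS-group tables, and
#' a JSON run-metadata file into `dir`.
#'
#' @param report a `sleepmr_report` from [run_pipeline()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "sleepmr_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(report$estimates, file.path(dir, "linear_estimates.tsv"))
  readr::write_tsv(report$descriptive, file.path(dir, "descriptive.tsv"))
  readr::write_tsv(report$screen, file.path(dir, "confounder_screen.tsv"))
  readr::write_tsv(report$strength, file.path(dir, "instrument_strength.tsv"))
  strata <- purrr::map_dfr(names(report$nonlinear), function(oc) {
    dplyr::mutate(report$nonlinear[[oc]]$strata, outcome = oc)
  })
  readr::write_tsv(strata, file.path(dir, "nonlinear_strata.tsv"))
  curves <- purrr::map_dfr(names(report$nonlinear), function(oc) {
    dplyr::mutate(report$nonlinear[[oc]]$curve, outcome = oc)
  })
  readr::write_csv(curves, file.path(dir, "nonlinear_curves.csv"))
  groups <- purrr::map_dfr(names(report$grs_groups), function(oc) {
    g <- report$grs_groups[[oc]]
    dplyr::mutate(g, outcome = oc, trend_p = attr(g, "trend_p"))
  })
  readr::write_tsv(groups, file.path(dir, "grs_groups.tsv"))
  jsonlite::write_json(report$meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
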