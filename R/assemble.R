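#' Assemble an analysis table from a simulated (or loaded) cohort
#'
#' Joins the per-participant genetic risk score, the phenotype table and
#' the derived metabolic components into the single tibble that the MR
#' estimators consume.
#'
#' @param cohort phenotype tibble (one row per participant).
#' @param genotypes dosage tibble with a `participant_id` column.
#' @param instruments instrument table for [compute_grs()].
#' @param weighted logical, passed to [compute_grs()].
#' @return Tibble: cohort columns + `grs` + the component flags and
#'   `mets` from [derive_components()].
#' @examples
#' sim <- simulate_cohort(sim_config(n_participants = 300, n_snps = 4))
#' dat <- assemble_analysis(sim$cohort, sim$genotypes, sim$instruments)
#' names(dat)
#' @export
assemble_analysis <- function(cohort, genotypes, instruments,
                              weighted = FALSE) {
  grs <- compute_grs(genotypes, instruments, weighted = weighted)
  comp <- derive_components(cohort)
  out <- dplyr::left_join(cohort, grs, by = "participant_id")
  dplyr::left_join(out, comp, by = "participant_id")
}
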