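#' Clean raw self-reported sleep duration responses
#'
#' Maps raw questionnaire responses to integer hours in `[4, 11]` or to an
#' exclusion with a reason. Negative numeric codes and non-numeric strings
#' (e.g. "Do not know", "Prefer not to answer") are treated as
#' non-response; numeric answers are rounded to the nearest hour and
#' excluded when outside the plausible 4-11 h range.
#'
#' @param raw numeric or character vector of raw responses.
#' @return A tibble with columns `raw`, `hours` (integer, `NA` when
#'   excluded), `kept` (logical) and `reason` (`NA`, `"non_response"` or
#'   `"out_of_range"`).
#' @examples
#' clean_sleep(c(7, 3, "Prefer not to answer", 11.4))
#' @export
clean_sleep <- function(raw) {
  x <- suppressWarnings(as.numeric(raw))
  non_response <- is.na(x) | x < 0
  hours <- as.integer(round(x))
  out_of_range <- !non_response & (hours < 4L | hours > 11L)
  kept <- !non_response & !out_of_range
  tibble(
    raw = as.character(raw),
    hours = ifelse(kept, hours, NA_integer_),
    kept = kept,
    reason = dplyr::case_when(
      non_response ~ "non_response",
      out_of_range ~ "out_of_range",
      TRUE ~ NA_character_
    )
  )
}

#' Categorize cleaned sleep duration
#'
#' Short is 6 h or less, normal is 7-8 h, long is 9 h or more.
#'
#' @param hours integer vector of cleaned sleep durations in `[4, 11]`.
#' @return factor with levels `short`, `normal`, `long`.
#' @examples
#' categorize_sleep(c(6, 7, 8, 9))
#' @export
categorize_sleep <- function(hours) {
  if (any(hours < 4 | hours > 11, na.rm = TRUE)) {
    abort("`hours` outside [4, 11]; run clean_sleep() first.")
  }
  factor(
    dplyr::case_when(
      hours <= 6 ~ "short",
      hours <= 8 ~ "normal",
      TRUE ~ "long"
    ),
    levels = c("short", "normal", "long")
  )
}

#' Derive metabolic syndrome components from biomarkers and medication
#'
#' Applies the standard component definitions to a biomarker table:
#' * central obesity: waist `>= 88` cm (women) / `>= 102` cm (men);
#' * high blood pressure: both SBP readings `>= 130` mmHg, or both DBP
#'   readings `>= 85` mmHg, or antihypertensive medication;
#' * dyslipidemia: HDL `< 1.0` mmol/L (men) / `< 1.3` mmol/L (women), or
#'   HDL-raising medication;
#' * hypertriglyceridemia: triglycerides `>= 1.7` mmol/L, or
#'   triglyceride-lowering medication;
#' * hyperglycemia: HbA1c `>= 42` mmol/mol, or diabetes medication.
#'
#' Metabolic syndrome (MetS) is three or more components. A medication
#' flag alone makes its component true regardless of the biomarker. A
#' missing biomarker gives `NA` for that component only; `n_components`
#' counts observed `TRUE`s, and `mets` is `NA` only when the missing
#' components could change whether the count reaches three.
#'
#' @param data data frame with columns `waist_cm`, `sbp_1`, `sbp_2`,
#'   `dbp_1`, `dbp_2`, `hdl_mmol`, `tg_mmol`, `hba1c_mmol`, `sex`
#'   (`"male"`/`"female"`) and logical `antihypertensive`, `hdl_drug`,
#'   `tg_drug`, `diabetes_drug`. Extra columns (ids, covariates) pass
#'   through untouched in the returned tibble's `participant_id` if
#'   present.
#' @return A tibble with `participant_id` (when present in `data`), the
#'   five component logicals, `n_components` and `mets`.
#' @examples
#' rec <- tibble::tibble(
#'   sex = "male", waist_cm = 103, sbp_1 = 120, sbp_2 = 118,
#'   dbp_1 = 78, dbp_2 = 76, hdl_mmol = 1.2, tg_mmol = 1.8,
#'   hba1c_mmol = 43, antihypertensive = FALSE, hdl_drug = FALSE,
#'   tg_drug = FALSE, diabetes_drug = FALSE
#' )
#' derive_components(rec)
#' @export
derive_components <- function(data) {
  need <- c("waist_cm", "sbp_1", "sbp_2", "dbp_1", "dbp_2", "hdl_mmol",
            "tg_mmol", "hba1c_mmol", "sex", "antihypertensive", "hdl_drug",
            "tg_drug", "diabetes_drug")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    abort(paste0("`data` lacks column(s): ", paste(missing, collapse = ", ")))
  }
  female <- data$sex == "female"

  flag_or_med <- function(flag, med) {
    # medication dominates: TRUE even when the biomarker is missing
    out <- flag
    out[med %in% TRUE] <- TRUE
    out
  }

  central_obesity <- data$waist_cm >= ifelse(female, 88, 102)
  high_bp <- flag_or_med(
    (data$sbp_1 >= 130 & data$sbp_2 >= 130) |
      (data$dbp_1 >= 85 & data$dbp_2 >= 85),
    data$antihypertensive
  )
  dyslipidemia <- flag_or_med(
    data$hdl_mmol < ifelse(female, 1.3, 1.0), data$hdl_drug
  )
  hypertriglyceridemia <- flag_or_med(data$tg_mmol >= 1.7, data$tg_drug)
  hyperglycemia <- flag_or_med(data$hba1c_mmol >= 42, data$diabetes_drug)

  comp <- cbind(central_obesity, high_bp, dyslipidemia,
                hypertriglyceridemia, hyperglycemia)
  n_true <- rowSums(comp, na.rm = TRUE)
  n_na <- rowSums(is.na(comp))
  mets <- n_true >= 3
  mets[!mets & n_true + n_na >= 3] <- NA

  out <- tibble(
    central_obesity = central_obesity,
    high_bp = high_bp,
    dyslipidemia = dyslipidemia,
    hypertriglyceridemia = hypertriglyceridemia,
    hyperglycemia = hyperglycemia,
    n_components = as.integer(n_true),
    mets = mets
  )
  if ("participant_id" %in% names(data)) {
    out <- dplyr::bind_cols(
      tibble(participant_id = data$participant_id), out)
  }
  out
}
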