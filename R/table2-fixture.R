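# Packaged roster of the 16 published atypical-diabetes cases, transcribed
# as plantable case specifications. The phenotypic pattern column is kept
# only as a held-out label for validation; the classifiers never read it.

NON_DRUG_REGIMENS <- c("diet", "diet-controlled", "diet controlled", "none",
                       "")

parse_regimen <- function(regimen) {
  drugs <- trimws(unlist(strsplit(regimen, ";", fixed = TRUE)))
  drugs <- drugs[!tolower(sub("\\s*\\(.*\\)$", "", drugs)) %in%
                   NON_DRUG_REGIMENS]
  if (length(drugs) == 0) {
    return(data.frame(drug_name = character(), drug_class = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(drug_name = tolower(drugs),
             drug_class = resolve_drug_class(drugs),
             stringsAsFactors = FALSE)
}

#' Case specifications of the published atypical-diabetes roster
#'
#' Returns the packaged transcription of the 16 confirmed atypical cases
#' (sex, current age, age at diagnosis with its upper-bound flag, BMI and
#' HbA1c ranges, treatment regimen, family history, adult-ketosis history
#' — documented only for case 1 — plus antibody/c-peptide status) in the
#' case-spec layout consumed by [plant_cases()]. The `pattern` column is
#' the published subtype label, held out for validation.
#'
#' @return data.frame of 16 case specifications.
#' @seealso [table2_cases()] for the derived case summaries.
#' @export
table2_case_specs <- function() {
  f <- system.file("extdata", "table2_cases.csv", package = "adscreen",
                   mustWork = TRUE)
  spec <- utils::read.csv(f, stringsAsFactors = FALSE)
  spec$family_members[is.na(spec$family_members)] <- ""
  spec
}

#' Case summaries of the published atypical-diabetes roster
#'
#' The chart-review summaries of the 16 packaged cases, computed from the
#' case specifications the same way [summarize_case()] would see them:
#' non-insulin medication counts are derived from the regimen through the
#' medication vocabulary, metabolic features at diagnosis from the BMI
#' range midpoint, and the observation span from current age minus age at
#' diagnosis.
#'
#' @return data.frame of 16 case summaries (columns of
#'   `CASE_SUMMARY_COLS` plus `case_id` and the held-out `pattern`).
#' @export
table2_cases <- function() {
  spec <- table2_case_specs()
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    s <- spec[i, ]
    meds <- parse_regimen(s$regimen)
    bmi_dx <- (s$bmi_min + s$bmi_max) / 2
    data.frame(
      patient_id = s$patient_id,
      sex = s$sex,
      current_age = s$current_age,
      age_at_diagnosis = s$age_at_diagnosis,
      age_at_diagnosis_is_upper_bound = s$age_at_diagnosis_is_upper_bound,
      bmi_min = s$bmi_min, bmi_max = s$bmi_max,
      hba1c_min = s$hba1c_min, hba1c_max = s$hba1c_max,
      n_noninsulin_dm_meds =
        length(intersect(unique(meds$drug_class), NONINSULIN_DM_CLASSES)),
      uses_insulin_long_term = s$uses_insulin_long_term,
      antibody_status = s$antibody_status,
      c_peptide_status = s$c_peptide_status,
      ketosis_history_adult = s$ketosis_history_adult,
      mody_genetic_test = "untested",
      family_history_diabetes = s$family_history_diabetes,
      multigenerational_family_history = s$multigenerational_family_history,
      pancreatic_disease_before_dx = FALSE,
      chronic_steroid_exposure_at_dx = FALSE,
      insulin_dependent_from_onset = FALSE,
      metabolic_features_at_dx = bmi_dx > 30,
      bmi_at_diagnosis = bmi_dx,
      observation_span_years = s$current_age - s$age_at_diagnosis,
      case_id = s$case_id,
      pattern = s$pattern,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
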