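# Deterministic rule engine standing in for expert chart review: assigns a
# diabetes-type category (atypical / a named not-atypical form / NMI when
# the chart lacks required information) and, for atypical cases, one of the
# three phenotypic subtypes KPD, MARD or ISNM.

DIABETES_CATEGORIES <- c("AD", "NMI", "typical_T1D", "typical_T2D", "MODY",
                         "LADA_autoimmune", "pancreatic_secondary",
                         "steroid_induced")
AD_SUBTYPES <- c("KPD", "MARD", "ISNM")

CASE_SUMMARY_COLS <- c("patient_id", "sex", "current_age",
                       "age_at_diagnosis", "age_at_diagnosis_is_upper_bound",
                       "bmi_min", "bmi_max", "hba1c_min", "hba1c_max",
                       "n_noninsulin_dm_meds", "uses_insulin_long_term",
                       "antibody_status", "c_peptide_status",
                       "ketosis_history_adult", "mody_genetic_test",
                       "family_history_diabetes",
                       "multigenerational_family_history",
                       "pancreatic_disease_before_dx",
                       "chronic_steroid_exposure_at_dx",
                       "insulin_dependent_from_onset",
                       "metabolic_features_at_dx", "bmi_at_diagnosis",
                       "observation_span_years")

#' Subtype-classifier configuration
#'
#' Thresholds of the atypical-diabetes subtype rules.
#'
#' @param mard_age_cutoff years; MARD requires diagnosis strictly after
#'   this age (soft clinical cutoff 60, implemented strictly so that a
#'   diagnosis exactly at 60 is not MARD).
#' @param mard_hba1c_ceiling percent; MARD requires every recorded HbA1c
#'   strictly below this (default 8.0, i.e. 64 mmol/mol).
#' @param mard_max_noninsulin_meds maximum count of distinct non-insulin
#'   diabetes drug classes compatible with MARD (default 2).
#' @param mard_min_span years; the mild course must be documented over at
#'   least this observation span (default 5).
#' @param youth_onset_age years; diagnoses strictly before this age count
#'   as youth onset in the diabetes-type rules (default 20).
#' @param mody_suspicion_age years; diagnosis strictly before this age
#'   combined with a multigenerational family history and no MODY genetic
#'   testing routes the case to NMI (default 35).
#' @return list of class `"subtype_config"`.
#' @export
subtype_config <- function(mard_age_cutoff = 60, mard_hba1c_ceiling = 8.0,
                           mard_max_noninsulin_meds = 2, mard_min_span = 5,
                           youth_onset_age = 20, mody_suspicion_age = 35) {
  stopifnot(mard_age_cutoff > 0, mard_hba1c_ceiling > 0,
            mard_max_noninsulin_meds >= 0, mard_min_span > 0)
  structure(list(mard_age_cutoff = mard_age_cutoff,
                 mard_hba1c_ceiling = mard_hba1c_ceiling,
                 mard_max_noninsulin_meds = mard_max_noninsulin_meds,
                 mard_min_span = mard_min_span,
                 youth_onset_age = youth_onset_age,
                 mody_suspicion_age = mody_suspicion_age),
            class = "subtype_config")
}

#' Condense a patient record into the chart-review summary
#'
#' Computes the view a chart reviewer works from: value ranges over all
#' recorded labs and BMI, the count of distinct non-insulin diabetes drug
#' classes ever used, derived antibody status (any positive ->
#' `positive`; else any negative -> `negative_documented`; else
#' `untested`), chart-review facts, and the observation span, measured as
#' the difference in calendar years between the first and last dated
#' record (diagnosis dates in EHRs are commonly documented at year
#' resolution, so spans are reported on the same scale).
#'
#' `uses_insulin_long_term` is taken from the chart facts when documented;
#' otherwise it falls back to medication evidence (`TRUE` if any
#' outpatient insulin exposure, else `FALSE`). `metabolic_features_at_dx`
#' is derived from the documented BMI at diagnosis (> 30 kg/m^2) when the
#' chart does not state it.
#'
#' @param x an `"adscreen_cohort"`.
#' @param id patient identifier.
#' @return one-row data.frame with the columns in `CASE_SUMMARY_COLS`.
#' @export
summarize_case <- function(x, id) {
  rec <- patient_record(x, id)
  dates <- c(rec$labs$date, rec$bmi$date, rec$medications$date,
             rec$diagnoses$date, rec$antibodies$date)
  ref_year <- if (length(dates) > 0) {
    as.integer(format(max(dates), "%Y"))
  } else NA_integer_
  span <- if (length(dates) > 0) {
    as.integer(format(max(dates), "%Y")) -
      as.integer(format(min(dates), "%Y"))
  } else NA_integer_
  rng <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) c(NA_real_, NA_real_) else range(v)
  }
  a1c <- rng(rec$labs$value[rec$labs$analyte == "HbA1c"])
  bmi <- rng(rec$bmi$value)
  ab <- rec$antibodies
  antibody_status <- if (nrow(ab) > 0 && any(ab$result == "positive")) {
    "positive"
  } else if (nrow(ab) > 0 && any(ab$result == "negative")) {
    "negative_documented"
  } else "untested"
  med_cls <- unique(rec$medications$drug_class)
  n_noninsulin <- sum(med_cls %in% NONINSULIN_DM_CLASSES)
  cf <- if (nrow(rec$chart_facts) > 0) rec$chart_facts[1, ] else NULL
  fact <- function(field, default = NA) {
    if (!is.null(cf) && !is.na(cf[[field]])) cf[[field]] else default
  }
  insulin_lt <- if (!is.null(cf) && !is.na(cf$long_term_insulin_use)) {
    cf$long_term_insulin_use
  } else {
    any(rec$medications$drug_class == "insulin" &
          rec$medications$setting == "outpatient")
  }
  bmi_dx <- fact("bmi_at_diagnosis", NA_real_)
  metabolic_dx <- if (!is.na(bmi_dx)) bmi_dx > 30 else NA
  data.frame(
    patient_id = id,
    sex = rec$patient$sex,
    current_age = if (!is.na(ref_year)) ref_year - rec$patient$birth_year
                  else NA_real_,
    age_at_diagnosis = fact("age_at_diagnosis", NA_real_),
    age_at_diagnosis_is_upper_bound =
      isTRUE(fact("age_at_diagnosis_is_upper_bound", FALSE)),
    bmi_min = bmi[1], bmi_max = bmi[2],
    hba1c_min = a1c[1], hba1c_max = a1c[2],
    n_noninsulin_dm_meds = n_noninsulin,
    uses_insulin_long_term = insulin_lt,
    antibody_status = antibody_status,
    c_peptide_status = fact("c_peptide_status", "untested"),
    ketosis_history_adult = fact("ketosis_history_adult", NA),
    mody_genetic_test = fact("mody_genetic_test", "untested"),
    family_history_diabetes = fact("family_history_diabetes", NA),
    multigenerational_family_history =
      fact("multigenerational_family_history", NA),
    pancreatic_disease_before_dx = fact("pancreatic_disease_before_dx", NA),
    chronic_steroid_exposure_at_dx =
      fact("chronic_steroid_exposure_at_dx", NA),
    insulin_dependent_from_onset = fact("insulin_dependent_from_onset", NA),
    metabolic_features_at_dx = metabolic_dx,
    bmi_at_diagnosis = bmi_dx,
    observation_span_years = span,
    stringsAsFactors = FALSE)
}

#' Summaries for several patients
#' @param x an `"adscreen_cohort"`.
#' @param ids patient identifiers.
#' @return data.frame, one row per id.
#' @export
summarize_cases <- function(x, ids) {
  do.call(rbind, lapply(ids, function(id) summarize_case(x, id)))
}

#' Default diabetes-type classification rules
#'
#' An ordered, first-match-wins rule list approximating an expert review
#' flow. Each rule is a list with `id`, `category` (or `"special"` for the
#' two NMI-producing rules) and `predicate`, a function of a case summary
#' returning `TRUE`/`FALSE` (`NA`-safe: undocumented facts never fire a
#' rule). The default order:
#'
#' 1. positive MODY genetic test -> `MODY`
#' 2. antibody positive with youth onset and insulin dependence from
#'    onset -> `typical_T1D`
#' 3. antibody positive otherwise -> `LADA_autoimmune`
#' 4. pancreatic disease before diagnosis -> `pancreatic_secondary`
#' 5. chronic steroid exposure at diagnosis -> `steroid_induced`
#' 6. metabolic features at diagnosis -> `typical_T2D`
#' 7. youth onset, insulin dependent from onset, low c-peptide ->
#'    `typical_T1D`
#' 8. MODY suspicion (diagnosis before 35 with multigenerational family
#'    history) without genetic testing -> `NMI`
#' 9. required chart information missing -> `NMI` (see
#'    [classify_diabetes_type()] for the required set)
#' 10. default -> `AD`
#'
#' The list is data: users can reorder, drop or add rules.
#'
#' @param config a [subtype_config()] (supplies the youth-onset and
#'   MODY-suspicion age cutoffs).
#' @return list of rules, class `"classifier_rules"`.
#' @export
default_classifier_rules <- function(config = subtype_config()) {
  youth <- config$youth_onset_age
  mody_age <- config$mody_suspicion_age
  rules <- list(
    list(id = "mody_genetic_positive", category = "MODY",
         predicate = function(cs) identical(cs$mody_genetic_test,
                                            "positive")),
    list(id = "antibody_positive_youth_onset", category = "typical_T1D",
         predicate = function(cs) {
           identical(cs$antibody_status, "positive") &&
             !is.na(cs$age_at_diagnosis) && cs$age_at_diagnosis < youth &&
             isTRUE(cs$insulin_dependent_from_onset)
         }),
    list(id = "antibody_positive", category = "LADA_autoimmune",
         predicate = function(cs) identical(cs$antibody_status,
                                            "positive")),
    list(id = "pancreatic_disease", category = "pancreatic_secondary",
         predicate = function(cs) isTRUE(cs$pancreatic_disease_before_dx)),
    list(id = "steroid_at_diagnosis", category = "steroid_induced",
         predicate = function(cs) {
           isTRUE(cs$chronic_steroid_exposure_at_dx)
         }),
    list(id = "metabolic_features", category = "typical_T2D",
         predicate = function(cs) isTRUE(cs$metabolic_features_at_dx)),
    list(id = "youth_insulin_dependent", category = "typical_T1D",
         predicate = function(cs) {
           !is.na(cs$age_at_diagnosis) && cs$age_at_diagnosis < youth &&
             isTRUE(cs$insulin_dependent_from_onset) &&
             identical(cs$c_peptide_status, "low")
         }),
    list(id = "mody_suspicion_untested", category = "NMI",
         predicate = function(cs) {
           !is.na(cs$age_at_diagnosis) &&
             cs$age_at_diagnosis < mody_age &&
             isTRUE(cs$multigenerational_family_history) &&
             identical(cs$mody_genetic_test, "untested")
         },
         nmi_reason = "mody_genetic_test")
  )
  structure(rules, class = "classifier_rules")
}

# required-information check: names of missing required fields, or
# character(0) when the chart is complete enough to call a type.
nmi_missing_fields <- function(cs) {
  reasons <- character(0)
  if (identical(cs$antibody_status, "untested") &&
      identical(cs$c_peptide_status, "untested")) {
    reasons <- c(reasons, "antibody_or_c_peptide_testing")
  }
  if (is.na(cs$age_at_diagnosis)) {
    reasons <- c(reasons, "age_at_diagnosis")
  }
  if (is.na(cs$bmi_at_diagnosis) && is.na(cs$metabolic_features_at_dx)) {
    reasons <- c(reasons, "bmi_or_metabolic_features_at_dx")
  }
  reasons
}

#' Classify diabetes type from a case summary
#'
#' Applies the ordered rule list (first match wins); if no named-form rule
#' fires, checks chart completeness and returns `NMI` (with the missing
#' fields as reasons) when required information is absent, otherwise the
#' terminal default `AD`. The required set is: antibody or c-peptide
#' testing documented, age at diagnosis documented, and BMI at diagnosis
#' or metabolic features at diagnosis documented.
#'
#' @param cs one-row case summary from [summarize_case()].
#' @param rules a `"classifier_rules"` list.
#' @return list of class `"classification_outcome"`: `category`,
#'   `subtype` (`"none"` here; see [classify_ad_subtype()]),
#'   `fired_rules` (ids evaluated, last one fired) and `nmi_reasons`.
#' @export
classify_diabetes_type <- function(cs, rules = default_classifier_rules()) {
  if (is.data.frame(cs)) cs <- as.list(cs[1, ])
  trace <- character(0)
  for (r in rules) {
    trace <- c(trace, r$id)
    if (isTRUE(r$predicate(cs))) {
      reasons <- if (identical(r$category, "NMI")) {
        r$nmi_reason %||% r$id
      } else character(0)
      return(structure(list(category = r$category, subtype = "none",
                            fired_rules = trace, nmi_reasons = reasons),
                       class = "classification_outcome"))
    }
  }
  missing <- nmi_missing_fields(cs)
  if (length(missing) > 0) {
    return(structure(list(category = "NMI", subtype = "none",
                          fired_rules = c(trace, "required_information"),
                          nmi_reasons = missing),
                     class = "classification_outcome"))
  }
  structure(list(category = "AD", subtype = "none",
                 fired_rules = c(trace, "default_atypical"),
                 nmi_reasons = character(0)),
            class = "classification_outcome")
}

#' @export
print.classification_outcome <- function(x, ...) {
  cat(sprintf("<classification_outcome> %s%s\n", x$category,
              if (x$subtype != "none") paste0(" / ", x$subtype) else ""))
  if (length(x$nmi_reasons) > 0) {
    cat("  missing:", paste(x$nmi_reasons, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Assign the atypical-diabetes subtype
#'
#' For a case already classified atypical, applies in order:
#'
#' * **KPD** (ketosis-prone, A-B+): documented history of ketosis in
#'   adulthood, antibody status not positive, and no long-term insulin
#'   use (preserved beta-cell function).
#' * **MARD** (mild age-related): diagnosis strictly after
#'   `mard_age_cutoff` (default 60), every recorded HbA1c strictly below
#'   `mard_hba1c_ceiling` (default 8%), at most
#'   `mard_max_noninsulin_meds` non-insulin diabetes drug classes, no
#'   long-term insulin, and the mild course documented over at least
#'   `mard_min_span` years of observation.
#' * **ISNM** (insulin-sufficient non-metabolic): the residual subtype.
#'
#' Ages recorded as upper bounds ("X or earlier") are used at their bound
#' value X; the flag is carried in the case summary for reporting.
#'
#' @param cs one-row case summary.
#' @param config a [subtype_config()].
#' @return `"KPD"`, `"MARD"` or `"ISNM"`.
#' @export
classify_ad_subtype <- function(cs, config = subtype_config()) {
  if (is.data.frame(cs)) cs <- as.list(cs[1, ])
  if (isTRUE(cs$ketosis_history_adult) &&
      !identical(cs$antibody_status, "positive") &&
      !isTRUE(cs$uses_insulin_long_term)) {
    return("KPD")
  }
  age <- cs$age_at_diagnosis
  span <- cs$observation_span_years
  if (!is.na(age) && age > config$mard_age_cutoff &&
      !is.na(cs$hba1c_max) && cs$hba1c_max < config$mard_hba1c_ceiling &&
      cs$n_noninsulin_dm_meds <= config$mard_max_noninsulin_meds &&
      !isTRUE(cs$uses_insulin_long_term) &&
      !is.na(span) && span >= config$mard_min_span) {
    return("MARD")
  }
  "ISNM"
}

#' Classify every candidate in a cohort
#'
#' Runs [summarize_case()], [classify_diabetes_type()] and — for cases
#' classified atypical — [classify_ad_subtype()] over a candidate set,
#' and tallies categories, subtypes and per-branch yields.
#'
#' @param candidates a `"candidate_set"` from [assemble_candidates()], or
#'   a character vector of patient ids (in which case no branch yields are
#'   computed).
#' @param x an `"adscreen_cohort"` containing every candidate.
#' @param rules a `"classifier_rules"` list.
#' @param config a [subtype_config()].
#' @return list of class `"cohort_classification"`: `outcomes`
#'   (data.frame patient_id / category / subtype / nmi_reasons),
#'   `category_tally`, `subtype_tally`, and `branch_yield` (data.frame
#'   branch / n_kept / n_ad / yield, `NA` yield for empty branches) when
#'   branch membership was supplied.
#' @export
classify_cohort <- function(candidates, x,
                            rules = default_classifier_rules(),
                            config = subtype_config()) {
  membership <- NULL
  if (inherits(candidates, "candidate_set")) {
    ids <- candidates$union_ids
    membership <- candidates$membership
  } else {
    ids <- sort(unique(as.character(candidates)))
  }
  unknown <- setdiff(ids, x$patients$patient_id)
  if (length(unknown) > 0) {
    stop("candidate id(s) not in cohort: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  rows <- lapply(ids, function(id) {
    cs <- summarize_case(x, id)
    out <- classify_diabetes_type(cs, rules)
    subtype <- if (out$category == "AD") {
      classify_ad_subtype(cs, config)
    } else "none"
    data.frame(patient_id = id, category = out$category, subtype = subtype,
               nmi_reasons = paste(out$nmi_reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  outcomes <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(patient_id = character(), category = character(),
               subtype = character(), nmi_reasons = character(),
               stringsAsFactors = FALSE)
  category_tally <- table(factor(outcomes$category,
                                 levels = DIABETES_CATEGORIES))
  subtype_tally <- table(factor(outcomes$subtype[outcomes$subtype != "none"],
                                levels = AD_SUBTYPES))
  branch_yield <- NULL
  if (!is.null(membership)) {
    ad_ids <- outcomes$patient_id[outcomes$category == "AD"]
    branch_yield <- do.call(rbind, lapply(seq_len(ncol(membership)),
      function(b) {
        kept <- rownames(membership)[membership[, b]]
        n_kept <- length(kept)
        n_ad <- length(intersect(kept, ad_ids))
        data.frame(branch = colnames(membership)[b], n_kept = n_kept,
                   n_ad = n_ad,
                   yield = if (n_kept > 0) n_ad / n_kept else NA_real_,
                   stringsAsFactors = FALSE)
      }))
  }
  structure(list(outcomes = outcomes, category_tally = category_tally,
                 subtype_tally = subtype_tally, branch_yield = branch_yield),
            class = "cohort_classification")
}

#' @export
print.cohort_classification <- function(x, ...) {
  cat(sprintf("<cohort_classification> %d candidates\n", nrow(x$outcomes)))
  tally <- x$category_tally[x$category_tally > 0]
  cat("  categories:", paste(names(tally), tally, sep = "=",
                             collapse = ", "), "\n")
  if (sum(x$subtype_tally) > 0) {
    cat("  AD subtypes:", paste(names(x$subtype_tally), x$subtype_tally,
                                sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
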