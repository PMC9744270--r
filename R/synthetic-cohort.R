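# Seeded generator of biobank-like cohorts with latent true diabetes types.
#
# Each patient is drawn from an archetype (nondiabetic, typical T2D,
# typical T1D, LADA, MODY-like, or one of three atypical forms), which
# fixes the distributions of their longitudinal labs, BMI trajectory,
# medication exposures, antibody testing pattern and chart-review facts.
# Curated-phenotype flags are then drawn with the stated PPV/NPV error
# structure relative to the latent truth.
#
# Flag-noise algebra (documented here because it is the load-bearing part):
# for a flag F with sensitivity s and positive predictive value p against a
# latent truth of prevalence π, the false-positive rate among
# non-cases that reproduces p in expectation is
#     P(F | not case) = s π (1 - p) / (p (1 - π)).
# For the T1D rule-out flag with negative predictive value v and coverage q
# (the fraction of non-T1D patients the rule-out reaches),
#     P(ruled_out | T1D) = q (1 - π) (1 - v) / (v π),
# which must lie in [0, 1 - s] so the rule-out never co-occurs with the
# high-PPV call; configurations violating this are rejected as infeasible.
# At low prevalence an NPV as low as 0.99 is only attainable when the
# rule-out covers a limited slice of the cohort, hence the default
# coverage of 0.12.

MED_POLICY_KEYS <- c("metformin", "sulfonylurea", "meglitinide", "TZD",
                     "DPP4i", "AGI", "GLP1RA", "SGLT2i",
                     "insulin_outpatient", "insulin_inpatient",
                     "systemic_steroid")

#' Archetype specification
#'
#' Distributional recipe for one latent patient archetype. All
#' distributions are artifact choices (the source biobank publishes no
#' lab-level distributions); they are chosen to be clinically plausible
#' and, for the atypical archetypes, to satisfy the base-algorithm
#' criteria by construction (`must_pass_base`).
#'
#' @param name archetype name.
#' @param prevalence fraction of the cohort.
#' @param labs list with entries `HDL`, `TG`, `HbA1c`, each
#'   `c(mean, sd, n)` where `n` is the expected (Poisson) record count.
#' @param bmi `c(mean, sd, n_extra, n_min)`: record count is
#'   `n_min + Poisson(n_extra)`.
#' @param meds named probability vector over `MED_POLICY_KEYS` (ever-use
#'   probability per drug class/setting).
#' @param antibody `c(p_tested, p_positive)`.
#' @param chart list of chart-fact distributions (see
#'   [default_archetypes()] source); `NULL` means chart facts are
#'   undocumented (the nondiabetic default).
#' @param must_pass_base if `TRUE`, lab/BMI draws are truncated so every
#'   patient survives the base algorithm (all HDL >= 50, TG <= 150, BMI
#'   <= 30 with at least three records, no CF code, no positive
#'   antibody) and phenotype flags are set favorably (`ml_t2d` TRUE,
#'   high-PPV T1D call FALSE, T1D rule-out TRUE).
#' @return list of class `"archetype_spec"`.
#' @export
archetype_spec <- function(name, prevalence, labs, bmi, meds = numeric(0),
                           antibody = c(0, 0), chart = NULL,
                           must_pass_base = FALSE) {
  stopifnot(prevalence >= 0, prevalence <= 1,
            all(vapply(labs, function(l) l[2] >= 0, logical(1))),
            bmi[2] >= 0)
  if (length(meds) > 0) {
    stopifnot(all(names(meds) %in% MED_POLICY_KEYS))
  }
  structure(list(name = name, prevalence = prevalence, labs = labs,
                 bmi = bmi, meds = meds, antibody = antibody,
                 chart = chart, must_pass_base = must_pass_base),
            class = "archetype_spec")
}

#' Phenotype-flag error specification
#'
#' Operating points of the simulated curated-phenotype flags, as published
#' for the source algorithms: T2D flag 88% sensitivity / 0.90 PPV; T1D
#' high-confidence flag at PPV 0.95 (sensitivity not published for that
#' operating point; the 0.78 sensitivity of the PPV-0.90 variant is used
#' as the default); T1D rule-out at NPV 0.99 with a default coverage of
#' 0.12 of non-T1D patients (see the algebra note in this file).
#'
#' @param t1d_flag_ppv,t1d_flag_sensitivity high-confidence T1D call.
#' @param t1d_ruleout_npv,t1d_ruleout_coverage T1D rule-out flag.
#' @param t2d_flag_ppv,t2d_flag_sensitivity T2D group flag.
#' @return list of class `"ml_flag_spec"`.
#' @export
ml_flag_spec <- function(t1d_flag_ppv = 0.95, t1d_flag_sensitivity = 0.78,
                         t1d_ruleout_npv = 0.99, t1d_ruleout_coverage = 0.12,
                         t2d_flag_ppv = 0.90, t2d_flag_sensitivity = 0.88) {
  vals <- c(t1d_flag_ppv, t1d_flag_sensitivity, t1d_ruleout_npv,
            t1d_ruleout_coverage, t2d_flag_ppv, t2d_flag_sensitivity)
  stopifnot(all(vals > 0), all(vals <= 1))
  structure(list(t1d_flag_ppv = t1d_flag_ppv,
                 t1d_flag_sensitivity = t1d_flag_sensitivity,
                 t1d_ruleout_npv = t1d_ruleout_npv,
                 t1d_ruleout_coverage = t1d_ruleout_coverage,
                 t2d_flag_ppv = t2d_flag_ppv,
                 t2d_flag_sensitivity = t2d_flag_sensitivity),
            class = "ml_flag_spec")
}

#' Default archetype mix
#'
#' Mirrors the published biobank composition: 6.22% latent typical T2D,
#' 0.63% typical T1D, atypical diabetes at 16/114,975 of the cohort split
#' 1:7:8 across KPD/MARD/ISNM, plus 0.2% LADA and 0.1% MODY-like as
#' confounder mass; the remainder is nondiabetic. `ad_prevalence` can be
#' raised for studies that need more atypical cases per simulated cohort.
#'
#' @param ad_prevalence total prevalence of the three atypical archetypes.
#' @param ad_split relative KPD/MARD/ISNM weights.
#' @return named list of `"archetype_spec"` objects.
#' @export
default_archetypes <- function(ad_prevalence = 16 / 114975,
                               ad_split = c(KPD = 1, MARD = 7, ISNM = 8)) {
  ad_split <- ad_split / sum(ad_split)
  ad <- ad_prevalence * ad_split
  known <- 0.0622 + 0.0063 + 0.002 + 0.001 + ad_prevalence
  stopifnot(known < 1)
  list(
    nondiabetic = archetype_spec(
      "nondiabetic", 1 - known,
      labs = list(HDL = c(55, 15, 2), TG = c(120, 55, 2),
                  HbA1c = c(5.4, 0.3, 0.3)),
      bmi = c(27, 5, 3, 2),
      meds = c(systemic_steroid = 0.05),
      antibody = c(0.01, 0.02),
      chart = NULL),
    typical_T2D = archetype_spec(
      "typical_T2D", 0.0622,
      labs = list(HDL = c(42, 10, 4), TG = c(185, 70, 4),
                  HbA1c = c(7.6, 1.3, 5)),
      bmi = c(32, 5, 4, 3),
      meds = c(metformin = 0.85, sulfonylurea = 0.35, DPP4i = 0.2,
               GLP1RA = 0.15, SGLT2i = 0.1, insulin_outpatient = 0.35),
      antibody = c(0.15, 0.02),
      chart = list(age_dx = c(40, 70), ketosis_p = 0.02,
                   c_peptide = c(0.05, 0.45, 0.5),
                   mody = c(0, 0.02, 0.98), fh_p = 0.5, multigen_p = 0.15,
                   pancreatic_p = 0.02, steroid_p = 0.03,
                   insulin_onset_p = 0.02, long_insulin_p = 0.3,
                   bmi_dx = c(32, 4))),
    typical_T1D = archetype_spec(
      "typical_T1D", 0.0063,
      labs = list(HDL = c(58, 13, 4), TG = c(95, 40, 4),
                  HbA1c = c(7.9, 1.4, 6)),
      bmi = c(24, 3, 4, 3),
      meds = c(insulin_outpatient = 0.98, insulin_inpatient = 0.3,
               metformin = 0.1),
      antibody = c(0.75, 0.85),
      chart = list(age_dx = c(5, 25), ketosis_p = 0.1,
                   c_peptide = c(0.7, 0.05, 0.25),
                   mody = c(0, 0.01, 0.99), fh_p = 0.15, multigen_p = 0.05,
                   pancreatic_p = 0.01, steroid_p = 0.01,
                   insulin_onset_p = 0.9, long_insulin_p = 0.95,
                   bmi_dx = c(22, 3))),
    LADA = archetype_spec(
      "LADA", 0.002,
      labs = list(HDL = c(55, 12, 4), TG = c(110, 45, 4),
                  HbA1c = c(7.5, 1.2, 5)),
      bmi = c(25, 3, 4, 3),
      meds = c(metformin = 0.6, sulfonylurea = 0.2,
               insulin_outpatient = 0.6),
      antibody = c(0.8, 0.9),
      chart = list(age_dx = c(30, 60), ketosis_p = 0.05,
                   c_peptide = c(0.4, 0.3, 0.3),
                   mody = c(0, 0.02, 0.98), fh_p = 0.3, multigen_p = 0.1,
                   pancreatic_p = 0.01, steroid_p = 0.02,
                   insulin_onset_p = 0.1, long_insulin_p = 0.6,
                   bmi_dx = c(25, 3))),
    MODY_like = archetype_spec(
      "MODY_like", 0.001,
      labs = list(HDL = c(60, 10, 3), TG = c(90, 30, 3),
                  HbA1c = c(6.8, 0.8, 4)),
      bmi = c(22.5, 2, 4, 3),
      meds = c(metformin = 0.5, sulfonylurea = 0.3,
               insulin_outpatient = 0.2),
      antibody = c(0.4, 0.02),
      chart = list(age_dx = c(12, 30), ketosis_p = 0.02,
                   c_peptide = c(0.05, 0.5, 0.45),
                   mody = c(0, 0.05, 0.95), fh_p = 0.95, multigen_p = 0.9,
                   pancreatic_p = 0, steroid_p = 0,
                   insulin_onset_p = 0.05, long_insulin_p = 0.15,
                   bmi_dx = c(22, 2))),
    AD_KPD = archetype_spec(
      "AD_KPD", unname(ad["KPD"]),
      labs = list(HDL = c(70, 8, 4), TG = c(90, 25, 4),
                  HbA1c = c(7.0, 1.5, 5)),
      bmi = c(24, 1.8, 2, 3),
      meds = c(metformin = 0.9, sulfonylurea = 0.2),
      antibody = c(0.6, 0),
      chart = list(age_dx = c(35, 55), ketosis_p = 1,
                   c_peptide = c(0, 1, 0),
                   mody = c(0, 0.3, 0.7), fh_p = 0.5, multigen_p = 0.2,
                   pancreatic_p = 0, steroid_p = 0,
                   insulin_onset_p = 0, long_insulin_p = 0,
                   bmi_dx = c(24, 1.5)),
      must_pass_base = TRUE),
    AD_MARD = archetype_spec(
      "AD_MARD", unname(ad["MARD"]),
      labs = list(HDL = c(72, 8, 4), TG = c(90, 25, 4),
                  HbA1c = c(6.3, 0.4, 5)),
      bmi = c(23.5, 1.8, 2, 3),
      meds = c(metformin = 0.5, sulfonylurea = 0.15, DPP4i = 0.15),
      antibody = c(0.6, 0),
      chart = list(age_dx = c(61, 80), ketosis_p = 0,
                   c_peptide = c(0, 1, 0),
                   mody = c(0, 0.2, 0.8), fh_p = 0.3, multigen_p = 0.1,
                   pancreatic_p = 0, steroid_p = 0,
                   insulin_onset_p = 0, long_insulin_p = 0,
                   bmi_dx = c(23.5, 1.5)),
      must_pass_base = TRUE),
    AD_ISNM = archetype_spec(
      "AD_ISNM", unname(ad["ISNM"]),
      labs = list(HDL = c(70, 8, 4), TG = c(95, 25, 4),
                  HbA1c = c(7.2, 1.0, 5)),
      bmi = c(23.5, 1.8, 2, 3),
      meds = c(metformin = 0.8, sulfonylurea = 0.3, GLP1RA = 0.2,
               insulin_outpatient = 0.2),
      antibody = c(0.6, 0),
      chart = list(age_dx = c(35, 60), ketosis_p = 0,
                   c_peptide = c(0, 1, 0),
                   mody = c(0, 0.2, 0.8), fh_p = 0.4, multigen_p = 0.1,
                   pancreatic_p = 0, steroid_p = 0,
                   insulin_onset_p = 0, long_insulin_p = 0.15,
                   bmi_dx = c(23.5, 1.5)),
      must_pass_base = TRUE)
  )
}

#' Generator configuration
#'
#' @param n_patients cohort size (>= 1).
#' @param seed mandatory integer seed; identical configurations produce
#'   byte-identical cohorts.
#' @param archetypes named list of [archetype_spec()]s whose prevalences
#'   sum to 1.
#' @param ml_flags an [ml_flag_spec()].
#' @param missingness per-field probability that a documented chart fact
#'   is removed (set to "not documented"). Default 0.13.
#' @return list of class `"generator_config"`.
#' @export
generator_config <- function(n_patients, seed,
                             archetypes = default_archetypes(),
                             ml_flags = ml_flag_spec(),
                             missingness = 0.13) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("a seed is mandatory")
  }
  if (n_patients < 1) stop("n_patients must be >= 1")
  prev <- vapply(archetypes, `[[`, numeric(1), "prevalence")
  if (abs(sum(prev) - 1) > 1e-8) {
    stop("archetype prevalences must sum to 1 (got ", sum(prev), ")")
  }
  stopifnot(missingness >= 0, missingness <= 1)
  structure(list(n_patients = as.integer(n_patients),
                 seed = as.integer(seed), archetypes = archetypes,
                 ml_flags = ml_flags, missingness = missingness),
            class = "generator_config")
}

OBS_START <- as.Date("2010-01-01")
OBS_END <- as.Date("2020-01-01")

random_dates <- function(n) {
  OBS_START + sample.int(as.integer(OBS_END - OBS_START), n,
                         replace = TRUE)
}

#' Generate a synthetic biobank cohort
#'
#' Draws `n_patients` from the configured archetype mix and materialises
#' per-patient longitudinal labs, BMI records, medication exposures,
#' antibody tests, chart facts (with the configured missingness injected
#' independently per field) and phenotype flags with the configured
#' PPV/NPV error structure. Reproducible: the same configuration always
#' yields an identical cohort; the caller's RNG state is restored on
#' exit.
#'
#' @param config a [generator_config()].
#' @return list with `cohort` (an `"adscreen_cohort"`) and `truth`
#'   (data.frame `patient_id` / `archetype`, the latent truth table).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_patients
  arch <- config$archetypes
  prev <- vapply(arch, `[[`, numeric(1), "prevalence")
  assignment <- sample(names(arch), n, replace = TRUE, prob = prev)
  ids <- sprintf("S%06d", seq_len(n))
  patients <- data.frame(
    patient_id = ids,
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.56, 0.44)),
    birth_year = sample(1930:1995, n, replace = TRUE),
    race_ethnicity = sample(RACE_LEVELS, n, replace = TRUE,
                            prob = c(0.845, 0.048, 0.025, 0.027, 0.025,
                                     0.03)),
    stringsAsFactors = FALSE)

  labs_acc <- list(); bmi_acc <- list(); med_acc <- list()
  ab_acc <- list(); dx_acc <- list(); chart_acc <- list()

  for (a in names(arch)) {
    sp <- arch[[a]]
    aids <- ids[assignment == a]
    n_a <- length(aids)
    if (n_a == 0) next
    labs_acc[[a]] <- gen_labs(aids, sp)
    bmi_acc[[a]] <- gen_bmi(aids, sp)
    med_acc[[a]] <- gen_meds(aids, sp)
    ab_acc[[a]] <- gen_antibodies(aids, sp)
    chart_acc[[a]] <- gen_chart(aids, sp)
    if (!sp$must_pass_base) {
      # sparse background CF diagnoses (an exclusion the base filter reads)
      has_cf <- stats::runif(n_a) < 0.001
      if (any(has_cf)) {
        dx_acc[[a]] <- data.frame(patient_id = aids[has_cf],
                                  code = "E84.0",
                                  date = random_dates(sum(has_cf)),
                                  stringsAsFactors = FALSE)
      }
    }
  }

  ml <- gen_ml_flags(ids, assignment, arch, config$ml_flags)
  chart <- do.call(rbind, unname(chart_acc))
  chart <- inject_missingness(chart, config$missingness)

  truth <- data.frame(patient_id = ids, archetype = assignment,
                      stringsAsFactors = FALSE)
  co <- cohort(patients = patients,
               labs = do.call(rbind, unname(labs_acc)),
               bmi = do.call(rbind, unname(bmi_acc)),
               medications = do.call(rbind, unname(med_acc)),
               diagnoses = if (length(dx_acc) > 0) {
                 do.call(rbind, unname(dx_acc))
               } else NULL,
               antibodies = do.call(rbind, unname(ab_acc)),
               ml_flags = ml,
               chart_facts = chart,
               provenance = sprintf("synthetic(n=%d, seed=%d)", n,
                                    config$seed),
               seed = config$seed)
  list(cohort = co, truth = truth)
}

gen_labs <- function(aids, sp) {
  out <- lapply(LAB_ANALYTES, function(an) {
    pol <- sp$labs[[an]]
    counts <- stats::rpois(length(aids), pol[3])
    total <- sum(counts)
    if (total == 0) return(NULL)
    v <- stats::rnorm(total, pol[1], pol[2])
    if (sp$must_pass_base) {
      v <- switch(an,
                  HDL = pmax(v, 51),
                  TG = pmin(pmax(v, 30), 148),
                  HbA1c = pmin(pmax(v, 4.2), 12))
    } else {
      v <- switch(an,
                  HDL = pmax(v, 5),
                  TG = pmax(v, 20),
                  HbA1c = pmin(pmax(v, 3.1), 19.9))
    }
    data.frame(patient_id = rep(aids, counts), analyte = an,
               value = round(v, 1), date = random_dates(total),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

gen_bmi <- function(aids, sp) {
  n_a <- length(aids)
  counts <- sp$bmi[4] + stats::rpois(n_a, sp$bmi[3])
  total <- sum(counts)
  v <- stats::rnorm(total, sp$bmi[1], sp$bmi[2])
  v <- if (sp$must_pass_base) pmin(pmax(v, 16), 29.4) else
    pmin(pmax(v, 10.5), 99)
  out <- data.frame(patient_id = rep(aids, counts), value = round(v, 1),
                    date = random_dates(total), stringsAsFactors = FALSE)
  if (sp$must_pass_base) {
    # anchor the observation window so the documented course spans the
    # full decade (the subtype rules read the span)
    anchor <- data.frame(
      patient_id = rep(aids, 2),
      value = round(pmin(pmax(stats::rnorm(2 * n_a, sp$bmi[1], sp$bmi[2]),
                              16), 29.4), 1),
      date = rep(c(as.Date("2012-06-15"), OBS_END), each = n_a),
      stringsAsFactors = FALSE)
    out <- rbind(out, anchor)
  }
  out
}

gen_meds <- function(aids, sp) {
  if (length(sp$meds) == 0) return(NULL)
  out <- lapply(names(sp$meds), function(key) {
    take <- stats::runif(length(aids)) < sp$meds[[key]]
    if (!any(take)) return(NULL)
    cls <- sub("^insulin_(out|in)patient$", "insulin", key)
    setting <- if (key == "insulin_inpatient") "inpatient" else "outpatient"
    name <- switch(cls, insulin = "insulin glargine",
                   metformin = "metformin", sulfonylurea = "glipizide",
                   meglitinide = "repaglinide", TZD = "pioglitazone",
                   DPP4i = "sitagliptin", AGI = "acarbose",
                   GLP1RA = "liraglutide", SGLT2i = "empagliflozin",
                   systemic_steroid = "prednisone", "other")
    data.frame(patient_id = aids[take], drug_name = name,
               drug_class = cls, setting = setting,
               date = random_dates(sum(take)), stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) NULL else do.call(rbind, out)
}

gen_antibodies <- function(aids, sp) {
  tested <- stats::runif(length(aids)) < sp$antibody[1]
  if (!any(tested)) return(NULL)
  tids <- aids[tested]
  n_ab <- sample(1:3, length(tids), replace = TRUE)
  positive <- stats::runif(length(tids)) < sp$antibody[2]
  if (sp$must_pass_base) positive[] <- FALSE
  rows <- lapply(seq_along(tids), function(i) {
    panel <- sample(ANTIBODY_PANEL, n_ab[i])
    res <- rep("negative", n_ab[i])
    if (positive[i]) res[1] <- "positive"
    data.frame(patient_id = tids[i], antibody = panel, result = res,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$date <- random_dates(nrow(out))
  out
}

gen_chart <- function(aids, sp) {
  n_a <- length(aids)
  if (is.null(sp$chart)) {
    # nothing documented: diabetes facts are absent, not false
    return(data.frame(
      patient_id = aids, age_at_diagnosis = NA_real_,
      age_at_diagnosis_is_upper_bound = FALSE,
      ketosis_history_adult = NA, c_peptide_status = "untested",
      mody_genetic_test = "untested", family_history_diabetes = NA,
      multigenerational_family_history = NA,
      pancreatic_disease_before_dx = NA,
      chronic_steroid_exposure_at_dx = NA,
      insulin_dependent_from_onset = NA, long_term_insulin_use = NA,
      bmi_at_diagnosis = NA_real_, stringsAsFactors = FALSE))
  }
  ch <- sp$chart
  draw_enum <- function(levels, probs) {
    sample(levels, n_a, replace = TRUE, prob = probs)
  }
  bmi_dx <- stats::rnorm(n_a, ch$bmi_dx[1], ch$bmi_dx[2])
  if (sp$must_pass_base) bmi_dx <- pmin(pmax(bmi_dx, 16), 29)
  data.frame(
    patient_id = aids,
    age_at_diagnosis = round(stats::runif(n_a, ch$age_dx[1],
                                          ch$age_dx[2])),
    age_at_diagnosis_is_upper_bound = FALSE,
    ketosis_history_adult = stats::runif(n_a) < ch$ketosis_p,
    c_peptide_status = draw_enum(C_PEPTIDE_LEVELS, ch$c_peptide),
    mody_genetic_test = draw_enum(MODY_TEST_LEVELS, ch$mody),
    family_history_diabetes = stats::runif(n_a) < ch$fh_p,
    multigenerational_family_history = stats::runif(n_a) < ch$multigen_p,
    pancreatic_disease_before_dx = stats::runif(n_a) < ch$pancreatic_p,
    chronic_steroid_exposure_at_dx = stats::runif(n_a) < ch$steroid_p,
    insulin_dependent_from_onset = stats::runif(n_a) < ch$insulin_onset_p,
    long_term_insulin_use = stats::runif(n_a) < ch$long_insulin_p,
    bmi_at_diagnosis = round(bmi_dx, 1),
    stringsAsFactors = FALSE)
}

# missingness: each documentable chart fact is independently removed with
# the configured probability; enum fields fall back to "untested"
inject_missingness <- function(chart, rate) {
  if (rate <= 0 || nrow(chart) == 0) return(chart)
  hide <- function(col, blank) {
    drop <- stats::runif(length(col)) < rate
    col[drop] <- blank
    col
  }
  logical_fields <- c("ketosis_history_adult", "family_history_diabetes",
                      "multigenerational_family_history",
                      "pancreatic_disease_before_dx",
                      "chronic_steroid_exposure_at_dx",
                      "insulin_dependent_from_onset",
                      "long_term_insulin_use")
  for (f in logical_fields) chart[[f]] <- hide(chart[[f]], NA)
  drop_age <- stats::runif(nrow(chart)) < rate
  chart$age_at_diagnosis[drop_age] <- NA_real_
  chart$age_at_diagnosis_is_upper_bound[drop_age] <- FALSE
  chart$bmi_at_diagnosis <- hide(chart$bmi_at_diagnosis, NA_real_)
  chart$c_peptide_status <- hide(chart$c_peptide_status, "untested")
  chart$mody_genetic_test <- hide(chart$mody_genetic_test, "untested")
  chart
}

gen_ml_flags <- function(ids, assignment, arch, spec) {
  n <- length(ids)
  prev <- vapply(arch, `[[`, numeric(1), "prevalence")
  is_ad <- vapply(arch[assignment], `[[`, logical(1), "must_pass_base")
  is_t1d <- assignment == "typical_T1D"
  is_t2d <- assignment == "typical_T2D"
  pi1 <- prev[["typical_T1D"]]

  # configured-prevalence feasibility check (a property of the spec, not
  # of one realized cohort)
  q <- spec$t1d_ruleout_coverage
  u_cfg <- q * (1 - pi1) * (1 - spec$t1d_ruleout_npv) /
    (spec$t1d_ruleout_npv * pi1)
  if (u_cfg > 1 - spec$t1d_flag_sensitivity + 1e-12) {
    stop(sprintf(paste0(
      "infeasible rule-out specification: NPV %.3f at T1D prevalence ",
      "%.4f with coverage %.3f would require P(ruled_out | T1D) = %.3f ",
      "> 1 - sensitivity = %.3f; lower t1d_ruleout_coverage"),
      spec$t1d_ruleout_npv, pi1, q, u_cfg,
      1 - spec$t1d_flag_sensitivity))
  }

  # calibrate against the realized archetype counts, so that conditional
  # on the truth table the flag errors are purely binomial at the stated
  # PPV/NPV operating points
  n1 <- sum(is_t1d); n2 <- sum(is_t2d)
  n_other1 <- sum(!is_t1d & !is_ad)
  n_other2 <- sum(!is_t2d & !is_ad)
  fp_rate <- function(sens, ppv, n_case, n_ctrl) {
    if (n_case == 0 || n_ctrl == 0) return(0)
    min(1, sens * n_case * (1 - ppv) / (ppv * n_ctrl))
  }
  fp2 <- fp_rate(spec$t2d_flag_sensitivity, spec$t2d_flag_ppv, n2,
                 n_other2)
  fp1 <- fp_rate(spec$t1d_flag_sensitivity, spec$t1d_flag_ppv, n1,
                 n_other1)
  u <- if (n1 == 0) 0 else {
    # truncation can only bind in very small cohorts; it errs toward a
    # cleaner rule-out (higher NPV)
    min(1 - spec$t1d_flag_sensitivity,
        q * n_other1 * (1 - spec$t1d_ruleout_npv) /
          (spec$t1d_ruleout_npv * n1))
  }

  ml_t2d <- logical(n)
  ml_t2d[is_t2d] <- stats::runif(sum(is_t2d)) < spec$t2d_flag_sensitivity
  other2 <- !is_t2d & !is_ad
  ml_t2d[other2] <- stats::runif(sum(other2)) < fp2
  ml_t2d[is_ad] <- TRUE

  high <- logical(n)
  high[is_t1d] <- stats::runif(sum(is_t1d)) < spec$t1d_flag_sensitivity
  other1 <- !is_t1d & !is_ad
  high[other1] <- stats::runif(sum(other1)) < fp1
  high[is_ad] <- FALSE

  ruled <- logical(n)
  sel_t1d <- is_t1d & !high
  ruled[sel_t1d] <- stats::runif(sum(sel_t1d)) <
    u / (1 - spec$t1d_flag_sensitivity)
  sel_other <- other1 & !high
  ruled[sel_other] <- stats::runif(sum(sel_other)) < q / (1 - fp1)
  ruled[is_ad] <- TRUE

  data.frame(patient_id = ids, ml_t2d = ml_t2d, ml_t1d_high_ppv = high,
             ml_t1d_ruled_out = ruled, stringsAsFactors = FALSE)
}

#' Plant fully specified cases into a cohort
#'
#' Materialises patient records whose derived chart-review summary equals
#' the requested case specification (see [table2_case_specs()] for the
#' layout), and appends them to an existing cohort — the standard way to
#' embed the packaged case roster in a synthetic haystack. Planted
#' patients receive favorable phenotype flags (T2D-flagged, T1D neither
#' called nor un-ruled-out) and safe HDL/TG records so that, when
#' `must_pass_base` is `TRUE` (the default), they are guaranteed to
#' survive the base algorithm; specifications that contradict the base
#' criteria (e.g. an HDL below 50 mg/dL or BMI above 30) are rejected.
#'
#' @param x an `"adscreen_cohort"` (may be empty: see [cohort()]).
#' @param specs data.frame of case specifications. Optional columns
#'   `hdl_min` (default 70) and `tg_max` (default 95) control the planted
#'   lipid records.
#' @param must_pass_base check the spec against the base-algorithm
#'   criteria and error on violation. Default `TRUE`.
#' @param reference_date date of the most recent planted record; current
#'   age is anchored to its year. Default `"2020-01-01"`.
#' @return the augmented `"adscreen_cohort"`.
#' @export
plant_cases <- function(x, specs, must_pass_base = TRUE,
                        reference_date = as.Date("2020-01-01")) {
  validate_cohort(x)
  if (is.null(specs) || nrow(specs) == 0) return(x)
  collide <- intersect(specs$patient_id, x$patients$patient_id)
  if (length(collide) > 0) {
    stop("planted id(s) already present in cohort: ",
         paste(collide, collapse = ", "))
  }
  if (anyDuplicated(specs$patient_id)) stop("duplicate ids among specs")
  if (!"hdl_min" %in% names(specs)) specs$hdl_min <- 70
  if (!"tg_max" %in% names(specs)) specs$tg_max <- 95
  if (must_pass_base) {
    bad <- specs$hdl_min < 50 | specs$tg_max > 150 | specs$bmi_max > 30
    if (any(bad)) {
      stop("case spec(s) violate the base-algorithm criteria: ",
           paste(specs$patient_id[bad], collapse = ", "))
    }
  }
  ref_year <- as.integer(format(reference_date, "%Y"))
  tabs <- lapply(seq_len(nrow(specs)), function(i) {
    materialize_case(specs[i, ], ref_year, reference_date)
  })
  bindt <- function(name) {
    do.call(rbind, c(list(x[[name]]),
                     lapply(tabs, `[[`, name)))
  }
  cohort(patients = bindt("patients"), labs = bindt("labs"),
         bmi = bindt("bmi"), medications = bindt("medications"),
         diagnoses = x$diagnoses, antibodies = bindt("antibodies"),
         ml_flags = bindt("ml_flags"), chart_facts = bindt("chart_facts"),
         provenance = x$provenance, seed = x$seed)
}

materialize_case <- function(s, ref_year, reference_date) {
  birth_year <- ref_year - s$current_age
  dx_year <- birth_year + s$age_at_diagnosis
  first_date <- as.Date(sprintf("%d-06-01", dx_year))
  mid_date <- as.Date(sprintf("%d-06-01",
                              floor((dx_year + ref_year) / 2)))
  late_date <- as.Date(sprintf("%d-12-01", ref_year - 1))
  bmi_mid <- (s$bmi_min + s$bmi_max) / 2
  meds <- parse_regimen(s$regimen)
  med_tab <- if (nrow(meds) > 0) {
    data.frame(patient_id = s$patient_id, drug_name = meds$drug_name,
               drug_class = meds$drug_class, setting = "outpatient",
               date = as.Date(sprintf("%d-06-01", ref_year - 1)),
               stringsAsFactors = FALSE)
  } else NULL
  labs <- data.frame(
    patient_id = s$patient_id,
    analyte = c("HDL", "HDL", "TG", "TG"),
    value = c(s$hdl_min, s$hdl_min + 5, s$tg_max - 5, s$tg_max),
    date = c(mid_date, late_date, mid_date, late_date),
    stringsAsFactors = FALSE)
  if (!is.na(s$hba1c_min)) {
    labs <- rbind(labs, data.frame(
      patient_id = s$patient_id, analyte = "HbA1c",
      value = c(s$hba1c_min, s$hba1c_max),
      date = c(first_date + 30, late_date), stringsAsFactors = FALSE))
  }
  ab_tab <- switch(s$antibody_status,
    negative_documented = data.frame(patient_id = s$patient_id,
                                     antibody = "GAD65",
                                     result = "negative", date = mid_date,
                                     stringsAsFactors = FALSE),
    positive = data.frame(patient_id = s$patient_id, antibody = "GAD65",
                          result = "positive", date = mid_date,
                          stringsAsFactors = FALSE),
    NULL)
  list(
    patients = data.frame(patient_id = s$patient_id, sex = s$sex,
                          birth_year = birth_year,
                          race_ethnicity = s$race,
                          stringsAsFactors = FALSE),
    labs = labs,
    bmi = data.frame(patient_id = s$patient_id,
                     value = c(s$bmi_min, bmi_mid, s$bmi_max),
                     date = c(first_date, mid_date, reference_date),
                     stringsAsFactors = FALSE),
    medications = med_tab,
    antibodies = ab_tab,
    ml_flags = data.frame(patient_id = s$patient_id, ml_t2d = TRUE,
                          ml_t1d_high_ppv = FALSE,
                          ml_t1d_ruled_out = TRUE,
                          stringsAsFactors = FALSE),
    chart_facts = data.frame(
      patient_id = s$patient_id,
      age_at_diagnosis = s$age_at_diagnosis,
      age_at_diagnosis_is_upper_bound = s$age_at_diagnosis_is_upper_bound,
      ketosis_history_adult = s$ketosis_history_adult,
      c_peptide_status = s$c_peptide_status,
      mody_genetic_test = "untested",
      family_history_diabetes = s$family_history_diabetes,
      multigenerational_family_history =
        s$multigenerational_family_history,
      pancreatic_disease_before_dx = FALSE,
      chronic_steroid_exposure_at_dx = FALSE,
      insulin_dependent_from_onset = FALSE,
      long_term_insulin_use = s$uses_insulin_long_term,
      bmi_at_diagnosis = bmi_mid,
      stringsAsFactors = FALSE))
}
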