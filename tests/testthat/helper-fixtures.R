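# In-code fixtures shared across test files.

# Small handcrafted cohort exercising every base/branch criterion:
#  H01 clean survivor (negative antibody, metformin + glipizide, no insulin)
#  H02 low HDL ever           H03 high TG ever
#  H04 BMI ever > 30          H05 only two qualifying BMI records
#  H06 cystic fibrosis code   H07 positive antibody
#  H08 outpatient insulin, untested antibodies, metformin only
#  H09 no medications at all, T1D flagged (high PPV)
#  H10 not in the ML T2D group
make_handcrafted_cohort <- function() {
  d <- function(s) as.Date(s)
  ids <- sprintf("H%02d", 1:10)
  patients <- data.frame(patient_id = ids,
                         sex = rep(c("F", "M"), 5),
                         birth_year = seq(1940, 1985, 5),
                         race_ethnicity = "White",
                         stringsAsFactors = FALSE)
  labs <- rbind(
    data.frame(patient_id = "H01", analyte = c("HDL", "TG", "HbA1c"),
               value = c(62, 120, 6.8), date = d("2015-03-01")),
    data.frame(patient_id = "H02", analyte = c("HDL", "HDL"),
               value = c(55, 49), date = d(c("2014-01-01", "2016-01-01"))),
    data.frame(patient_id = "H03", analyte = c("TG", "TG"),
               value = c(140, 151), date = d(c("2014-01-01", "2016-01-01"))),
    data.frame(patient_id = "H08", analyte = "HDL", value = 70,
               date = d("2015-01-01")),
    data.frame(patient_id = "H09", analyte = "HDL", value = 75,
               date = d("2015-01-01")))
  three_bmi <- function(id, values, years = c(2013, 2015, 2017)) {
    data.frame(patient_id = id, value = values,
               date = d(sprintf("%d-06-01", years)))
  }
  bmi <- rbind(
    three_bmi("H01", c(22, 23, 24)),
    three_bmi("H02", c(24, 24, 25)),
    three_bmi("H03", c(23, 24, 25)),
    three_bmi("H04", c(28, 29, 29, 31), years = c(2012, 2013, 2015, 2017)),
    data.frame(patient_id = "H05", value = c(22, 23),
               date = d(c("2014-06-01", "2016-06-01"))),
    three_bmi("H06", c(21, 22, 22)),
    three_bmi("H07", c(23, 24, 24)),
    three_bmi("H08", c(24, 25, 26)),
    three_bmi("H09", c(22, 23, 23)),
    three_bmi("H10", c(27, 28, 29)))
  medications <- rbind(
    data.frame(patient_id = "H01", drug_name = c("metformin", "glipizide"),
               drug_class = c("metformin", "sulfonylurea"),
               setting = "outpatient", date = d("2016-02-01")),
    data.frame(patient_id = "H08",
               drug_name = c("insulin glargine", "metformin"),
               drug_class = c("insulin", "metformin"),
               setting = "outpatient", date = d("2015-05-01")),
    data.frame(patient_id = "H04", drug_name = "insulin lispro",
               drug_class = "insulin", setting = "inpatient",
               date = d("2015-05-01")))
  diagnoses <- data.frame(patient_id = "H06", code = "E84.0",
                          date = d("2012-01-01"), stringsAsFactors = FALSE)
  antibodies <- rbind(
    data.frame(patient_id = "H01", antibody = "GAD65", result = "negative",
               date = d("2015-01-01")),
    data.frame(patient_id = "H07", antibody = c("GAD65", "ZnT8"),
               result = c("negative", "positive"), date = d("2015-01-01")))
  ml_flags <- data.frame(
    patient_id = ids,
    ml_t2d = c(rep(TRUE, 9), FALSE),
    ml_t1d_high_ppv = c(rep(FALSE, 8), TRUE, FALSE),
    ml_t1d_ruled_out = c(rep(TRUE, 8), FALSE, FALSE),
    stringsAsFactors = FALSE)
  cohort(patients = patients, labs = labs, bmi = bmi,
         medications = medications, diagnoses = diagnoses,
         antibodies = antibodies, ml_flags = ml_flags,
         provenance = "handcrafted test cohort")
}

# Minimal random cohort (medications/flags/antibodies only) for branch
# property sweeps; cheap enough to build by the thousand.
make_mini_cohort <- function(n = 15) {
  ids <- sprintf("M%03d", seq_len(n))
  patients <- data.frame(patient_id = ids, sex = "F", birth_year = 1960L,
                         race_ethnicity = "White", stringsAsFactors = FALSE)
  pick <- function(p) stats::runif(n) < p
  med_rows <- list()
  classes <- c("metformin", "sulfonylurea", "DPP4i", "GLP1RA", "insulin",
               "insulin")
  settings <- c(rep("outpatient", 5), "inpatient")
  for (k in seq_along(classes)) {
    take <- pick(0.4)
    if (any(take)) {
      med_rows[[k]] <- data.frame(
        patient_id = ids[take], drug_name = "x",
        drug_class = classes[k], setting = settings[k],
        date = as.Date("2015-01-01"), stringsAsFactors = FALSE)
    }
  }
  ab_take <- pick(0.5)
  antibodies <- if (any(ab_take)) {
    data.frame(patient_id = ids[ab_take], antibody = "GAD65",
               result = "negative", date = as.Date("2015-01-01"),
               stringsAsFactors = FALSE)
  } else NULL
  high <- pick(0.2)
  ruled <- !high & pick(0.5)
  ml_flags <- data.frame(patient_id = ids, ml_t2d = TRUE,
                         ml_t1d_high_ppv = high, ml_t1d_ruled_out = ruled,
                         stringsAsFactors = FALSE)
  cohort(patients = patients,
         medications = if (length(med_rows) > 0) {
           do.call(rbind, med_rows)
         } else NULL,
         antibodies = antibodies, ml_flags = ml_flags,
         provenance = "mini random cohort")
}
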