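test_that("entity tables are joined to the right patients on read", {
  bundle <- withr::local_tempdir()
  writeLines(c("patient_id,sex,birth_year,race_ethnicity",
               "P1,F,1950,White", "P2,M,1960,Black", "P3,F,1970,Asian"),
             file.path(bundle, "patients.csv"))
  writeLines(c("patient_id,analyte,value,date",
               "P1,HDL,62,2015-01-02", "P3,HbA1c,6.5,2016"),
             file.path(bundle, "labs.csv"))
  co <- read_cohort(bundle)
  expect_equal(n_patients(co), 3)
  expect_equal(patient_record(co, "P1")$labs$value, 62)
  expect_equal(nrow(patient_record(co, "P2")$labs), 0)
  # year-only date mapped to mid-year
  expect_equal(patient_record(co, "P3")$labs$date, as.Date("2016-07-01"))
})

test_that("invalid bundles are rejected", {
  bundle <- withr::local_tempdir()
  writeLines(c("patient_id,sex,birth_year,race_ethnicity",
               "P1,F,1950,White", "P1,M,1960,Black"),
             file.path(bundle, "patients.csv"))
  expect_error(read_cohort(bundle), "duplicate patient_id")

  bundle2 <- withr::local_tempdir()
  writeLines(c("patient_id,sex,birth_year,race_ethnicity", "P1,F,1950,White"),
             file.path(bundle2, "patients.csv"))
  writeLines(c("patient_id,analyte,value,date", "P9,HDL,60,2015-01-01"),
             file.path(bundle2, "labs.csv"))
  expect_error(read_cohort(bundle2), "unknown patient")

  bundle3 <- withr::local_tempdir()
  expect_error(read_cohort(bundle3), "patients table")

  bundle4 <- withr::local_tempdir()
  writeLines(c("patient_id,sex,birth_year,race_ethnicity", "P1,F,1950,White"),
             file.path(bundle4, "patients.csv"))
  writeLines(c("patient_id,analyte,value,date", "P1,HDL,sixty,2015-01-01"),
             file.path(bundle4, "labs.csv"))
  expect_error(read_cohort(bundle4), "unparseable numeric")
})

test_that("cohort invariants are enforced", {
  base <- make_handcrafted_cohort()
  bad_flags <- base$ml_flags
  bad_flags$ml_t1d_high_ppv[1] <- TRUE
  bad_flags$ml_t1d_ruled_out[1] <- TRUE
  expect_error(cohort(base$patients, ml_flags = bad_flags),
               "mutually exclusive")
  bad_labs <- data.frame(patient_id = "H01", analyte = "HbA1c",
                         value = 25, date = as.Date("2015-01-01"))
  expect_error(cohort(base$patients, labs = bad_labs), "HbA1c")
  bad_bmi <- data.frame(patient_id = "H01", value = 8,
                        date = as.Date("2015-01-01"))
  expect_error(cohort(base$patients, bmi = bad_bmi), "BMI")
})

test_that("write/read round-trip is lossless and deterministic", {
  g <- generate_cohort(generator_config(300, seed = 101,
                                        archetypes = default_archetypes(
                                          ad_prevalence = 0.05)))
  co <- g$cohort
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(co, d1)
  back <- read_cohort(d1)
  # field-by-field equality after the writer's canonical ordering
  for (tab in c("patients", "labs", "bmi", "medications", "diagnoses",
                "antibodies", "ml_flags", "chart_facts")) {
    orig <- co[[tab]]
    if (nrow(orig) > 0) {
      orig <- orig[do.call(order, unname(as.list(orig))), , drop = FALSE]
    }
    rownames(orig) <- NULL
    expect_equal(back[[tab]], orig, info = tab)
  }
  expect_equal(back$provenance, co$provenance)
  expect_equal(back$seed, co$seed)
  # two writes are byte-identical
  write_cohort(co, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
})

test_that("an empty cohort writes header-only tables that read back", {
  empty <- cohort(NULL, provenance = "empty")
  d <- withr::local_tempdir()
  write_cohort(empty, d)
  expect_true(all(file.exists(file.path(d, paste0(
    c("patients", "labs", "bmi", "medications", "diagnoses", "antibodies",
      "ml_flags", "chart_facts"), ".csv")))))
  expect_equal(n_patients(read_cohort(d)), 0)
})

test_that("json-lines cohorts are accepted", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    paste0('{"patient_id":"J1","sex":"F","birth_year":1955,',
           '"race_ethnicity":"White",',
           '"labs":[{"analyte":"HDL","value":66,"date":"2014-05-01"}],',
           '"ml_flags":{"ml_t2d":true,"ml_t1d_high_ppv":false,',
           '"ml_t1d_ruled_out":true}}'),
    paste0('{"patient_id":"J2","sex":"M","birth_year":1940,',
           '"race_ethnicity":"Asian"}')), f)
  co <- read_cohort(f)
  expect_equal(sort(co$patients$patient_id), c("J1", "J2"))
  expect_equal(co$labs$value, 66)
  expect_true(co$ml_flags$ml_t2d[co$ml_flags$patient_id == "J1"])
})

test_that("most_recent picks max date, breaks ties by value, is
           permutation-invariant", {
  df <- data.frame(value = c(24.0, 22.5),
                   date = as.Date(c("2018-01-01", "2020-01-01")))
  expect_equal(most_recent(df)$value, 22.5)
  expect_null(most_recent(df[0, ]))
  tie <- data.frame(value = c(24.0, 25.0),
                    date = as.Date(c("2020-01-01", "2020-01-01")))
  expect_equal(most_recent(tie)$value, 25.0)
  set.seed(5)
  for (i in 1:20) {
    n <- sample(1:8, 1)
    df <- data.frame(value = round(runif(n, 15, 35), 1),
                     date = as.Date("2010-01-01") +
                       sample(0:1000, n, replace = TRUE))
    perm <- df[sample(n), ]
    expect_equal(most_recent(perm), most_recent(df))
  }
})

test_that("drug names resolve through the vocabulary with a warning on
           unknowns", {
  expect_equal(resolve_drug_class(c("Metformin", "glipizide",
                                    "Metformin (discontinued)",
                                    "basal insulin")),
               c("metformin", "sulfonylurea", "metformin", "insulin"))
  expect_warning(cls <- resolve_drug_class("novel-drug-x"), "other")
  expect_equal(cls, "other")
})
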