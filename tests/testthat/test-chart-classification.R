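test_that("case summaries derive ranges, med counts and antibody status", {
  bg <- cohort(NULL, provenance = "empty")
  hay <- plant_cases(bg, table2_case_specs())
  cs6 <- summarize_case(hay, "AD-06")
  expect_equal(c(cs6$hba1c_min, cs6$hba1c_max), c(6.1, 6.4))
  cs16 <- summarize_case(hay, "AD-16")
  expect_true(is.na(cs16$hba1c_max))       # no HbA1c on record
  cs3 <- summarize_case(hay, "AD-03")
  expect_equal(cs3$n_noninsulin_dm_meds, 2)  # metformin + glipizide
  expect_equal(cs3$antibody_status, "negative_documented")
  # insulin counts toward the regimen but not the non-insulin tally
  cs2 <- summarize_case(hay, "AD-02")
  expect_equal(cs2$n_noninsulin_dm_meds, 2)  # metformin + liraglutide
  expect_true(cs2$uses_insulin_long_term)
  # observation span measured in calendar years covers dx to present
  expect_equal(cs6$observation_span_years, 74 - 68)
})

test_that("diabetes-type rules fire in the documented order", {
  base_case <- table2_cases()[3, ]   # a documented atypical case
  expect_equal(classify_diabetes_type(base_case)$category, "AD")

  mody <- base_case; mody$mody_genetic_test <- "positive"
  expect_equal(classify_diabetes_type(mody)$category, "MODY")

  lada <- base_case; lada$antibody_status <- "positive"
  out <- classify_diabetes_type(lada)
  expect_equal(out$category, "LADA_autoimmune")
  expect_equal(utils::tail(out$fired_rules, 1), "antibody_positive")

  t1d <- base_case
  t1d$antibody_status <- "positive"
  t1d$age_at_diagnosis <- 12
  t1d$insulin_dependent_from_onset <- TRUE
  expect_equal(classify_diabetes_type(t1d)$category, "typical_T1D")

  panc <- base_case; panc$pancreatic_disease_before_dx <- TRUE
  expect_equal(classify_diabetes_type(panc)$category,
               "pancreatic_secondary")

  ster <- base_case; ster$chronic_steroid_exposure_at_dx <- TRUE
  expect_equal(classify_diabetes_type(ster)$category, "steroid_induced")

  t2d <- base_case; t2d$metabolic_features_at_dx <- TRUE
  expect_equal(classify_diabetes_type(t2d)$category, "typical_T2D")
})

test_that("MODY suspicion without genetic testing and missing chart data
           route to NMI", {
  cs <- table2_cases()[3, ]
  cs$age_at_diagnosis <- 30
  cs$multigenerational_family_history <- TRUE
  out <- classify_diabetes_type(cs)
  expect_equal(out$category, "NMI")
  expect_equal(out$nmi_reasons, "mody_genetic_test")
  # same facts with a negative genetic test stay atypical
  cs$mody_genetic_test <- "negative"
  expect_equal(classify_diabetes_type(cs)$category, "AD")

  untested <- table2_cases()[5, ]
  untested$antibody_status <- "untested"
  untested$c_peptide_status <- "untested"
  out2 <- classify_diabetes_type(untested)
  expect_equal(out2$category, "NMI")
  expect_true("antibody_or_c_peptide_testing" %in% out2$nmi_reasons)
})

test_that("nulling required facts of an atypical case yields NMI, never a
           named form", {
  cases <- table2_cases()
  nullings <- list(
    function(cs) { cs$age_at_diagnosis <- NA; cs },
    function(cs) { cs$antibody_status <- "untested"
                   cs$c_peptide_status <- "untested"; cs },
    function(cs) { cs$bmi_at_diagnosis <- NA
                   cs$metabolic_features_at_dx <- NA; cs },
    function(cs) { cs$ketosis_history_adult <- NA; cs })
  for (i in seq_len(nrow(cases))) {
    for (f in nullings) {
      out <- classify_diabetes_type(f(cases[i, ]))
      expect_true(out$category %in% c("AD", "NMI"),
                  info = sprintf("case %d", i))
    }
  }
})

test_that("subtype rules reproduce the published roster labels", {
  cases <- table2_cases()
  sub <- vapply(seq_len(nrow(cases)),
                function(i) classify_ad_subtype(cases[i, ]), character(1))
  expect_equal(sub, cases$pattern)
  tally <- table(factor(sub, levels = c("KPD", "MARD", "ISNM")))
  expect_equal(unname(c(tally)), c(1, 7, 8))
})

test_that("subtype boundaries behave as configured", {
  mard <- table2_cases()[8, ]   # dx 67, HbA1c <= 7.3, one agent
  expect_equal(classify_ad_subtype(mard), "MARD")
  # diagnosis exactly at the age cutoff is not MARD (strict >)
  at60 <- mard; at60$age_at_diagnosis <- 60
  expect_equal(classify_ad_subtype(at60), "ISNM")
  # HbA1c at the ceiling fails the strict < test
  hot <- mard; hot$hba1c_max <- 8.0
  expect_equal(classify_ad_subtype(hot), "ISNM")
  # too short an observation span
  short <- mard; short$observation_span_years <- 4
  expect_equal(classify_ad_subtype(short), "ISNM")
  # ketosis dominates: KPD even at MARD-compatible age
  keto <- mard; keto$ketosis_history_adult <- TRUE
  expect_equal(classify_ad_subtype(keto), "KPD")
  # but not under long-term insulin (beta-cell failure)
  keto$uses_insulin_long_term <- TRUE
  expect_false(classify_ad_subtype(keto) == "KPD")
  # config softness: lowering the age cutoff reclassifies
  expect_equal(classify_ad_subtype(at60,
                                   subtype_config(mard_age_cutoff = 55)),
               "MARD")
})

test_that("cohort-level classification tallies categories and computes
           branch yields", {
  bg <- generate_cohort(generator_config(
    300, seed = 17, archetypes = default_archetypes(ad_prevalence = 0)))
  hay <- plant_cases(bg$cohort, table2_case_specs())
  kept <- apply_base_algorithm(hay)$kept
  cs <- assemble_candidates(run_branches(hay, kept))
  cl <- classify_cohort(cs, hay)
  expect_equal(unname(c(cl$subtype_tally)), c(1, 7, 8))
  expect_true(all(cl$outcomes$subtype == "none" |
                    cl$outcomes$category == "AD"))
  # branch yields consistent with a direct recount
  ad_ids <- cl$outcomes$patient_id[cl$outcomes$category == "AD"]
  for (b in seq_len(6)) {
    keptb <- rownames(cs$membership)[cs$membership[, b]]
    expect_equal(cl$branch_yield$n_ad[b], length(intersect(keptb, ad_ids)))
  }
  # empty candidate sets produce empty tables
  empty <- classify_cohort(character(0), hay)
  expect_equal(nrow(empty$outcomes), 0)
  # unknown candidate ids are an error
  expect_error(classify_cohort(c("NOPE"), hay), "not in cohort")
})

test_that("classification outcomes are independent of candidate order", {
  bg <- cohort(NULL, provenance = "empty")
  hay <- plant_cases(bg, table2_case_specs())
  ids <- table2_case_specs()$patient_id
  a <- classify_cohort(ids, hay)
  b <- classify_cohort(rev(ids), hay)
  expect_identical(a$outcomes, b$outcomes)
})
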