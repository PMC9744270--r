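labs_df <- function(analyte, values) {
  data.frame(patient_id = rep("X", length(values)),
             analyte = rep(analyte, length(values)), value = values,
             date = as.Date("2015-01-01") + seq_along(values))
}

test_that("threshold crossings are strict and one-sided", {
  expect_true(ever_outside(labs_df("HDL", c(55, 49, 60)), "HDL", 50,
                           "below"))
  expect_false(ever_outside(labs_df("HDL", numeric(0)), "HDL", 50, "below"))
  # boundary value does not trigger ("greater than 150")
  expect_false(ever_outside(labs_df("TG", 150), "TG", 150, "above"))
  expect_true(ever_outside(labs_df("TG", 150.1), "TG", 150, "above"))
  # other analytes are invisible to the check
  expect_false(ever_outside(labs_df("TG", 49), "HDL", 50, "below"))
})

test_that("engagement requires three qualifying BMI records", {
  bmi <- function(v) data.frame(patient_id = "X", value = v,
                                date = as.Date("2015-01-01") + seq_along(v))
  expect_true(has_engagement(bmi(c(22, 23, 24))))
  expect_false(has_engagement(bmi(c(22, 23))))
  # a record above the normal ceiling does not count
  expect_false(has_engagement(bmi(c(22, 23, 31))))
  cfg <- base_filter_config(min_bmi_count = 2)
  expect_true(has_engagement(bmi(c(22, 23)), cfg))
})

test_that("CF codes match by prefix and antibodies by any positive", {
  dx <- function(codes) data.frame(patient_id = rep("X", length(codes)),
                                   code = codes,
                                   date = rep(as.Date("2015-01-01"),
                                              length(codes)))
  expect_true(has_cf(dx("E84.0")))
  expect_true(has_cf(dx("277.01")))
  expect_false(has_cf(dx(character(0))))
  expect_false(has_cf(dx("E11.9")))
  ab <- function(a, r) data.frame(patient_id = rep("X", length(a)),
                                  antibody = a, result = r,
                                  date = rep(as.Date("2015-01-01"),
                                             length(a)))
  expect_true(has_positive_antibody(ab(c("GAD65", "ZnT8"),
                                       c("negative", "positive"))))
  expect_false(has_positive_antibody(ab("GAD65", "negative")))
  expect_false(has_positive_antibody(ab(character(0), character(0))))
})

test_that("base algorithm tags each exclusion and keeps clean records", {
  co <- make_handcrafted_cohort()
  res <- apply_base_algorithm(co)
  expect_equal(res$input_size, 9)          # H10 is not ML-T2D flagged
  expect_equal(res$excluded$metabolic_hdl, "H02")
  expect_equal(res$excluded$metabolic_tg, "H03")
  expect_equal(res$excluded$metabolic_bmi, "H04")
  expect_equal(res$excluded$engagement, "H05")
  expect_equal(res$excluded$cf, "H06")
  expect_equal(res$excluded$antibody, "H07")
  expect_equal(res$kept, c("H01", "H08", "H09"))
  # accounting: kept + excluded-by->=1 partitions the input
  expect_equal(length(res$kept) + length(unique(unlist(res$excluded))),
               res$input_size)
})

test_that("a cohort without ML-T2D patients yields an empty result", {
  co <- make_handcrafted_cohort()
  fl <- co$ml_flags; fl$ml_t2d <- FALSE
  co2 <- cohort(co$patients, co$labs, co$bmi, co$medications, co$diagnoses,
                co$antibodies, fl, provenance = "no ml_t2d")
  res <- apply_base_algorithm(co2)
  expect_equal(res$input_size, 0)
  expect_length(res$kept, 0)
})

test_that("base algorithm matches the flat-scan oracle on synthetic
           cohorts", {
  g <- generate_cohort(generator_config(
    2000, seed = 31, archetypes = default_archetypes(ad_prevalence = 0.01)))
  res <- apply_base_algorithm(g$cohort)
  expect_equal(res$kept, oracle_base_kept(g$cohort))
  # and with tightened thresholds
  cfg <- base_filter_config(hdl_floor = 60, tg_ceiling = 120,
                            bmi_ceiling = 27)
  expect_equal(apply_base_algorithm(g$cohort, cfg)$kept,
               oracle_base_kept(g$cohort, cfg))
})

test_that("base algorithm is idempotent and monotone in its thresholds", {
  g <- generate_cohort(generator_config(
    1500, seed = 77, archetypes = default_archetypes(ad_prevalence = 0.01)))
  co <- g$cohort
  res <- apply_base_algorithm(co)
  # idempotence: restrict the cohort to the kept set and re-run
  keep_tab <- function(t) t[t$patient_id %in% res$kept, , drop = FALSE]
  co_kept <- cohort(keep_tab(co$patients), keep_tab(co$labs),
                    keep_tab(co$bmi), keep_tab(co$medications),
                    keep_tab(co$diagnoses), keep_tab(co$antibodies),
                    keep_tab(co$ml_flags), keep_tab(co$chart_facts),
                    provenance = "kept subset")
  res2 <- apply_base_algorithm(co_kept)
  expect_equal(res2$kept, res$kept)
  expect_equal(res2$input_size, length(res$kept))
  # relaxing any threshold never shrinks the kept set
  relaxed <- list(base_filter_config(hdl_floor = 40),
                  base_filter_config(tg_ceiling = 200),
                  base_filter_config(bmi_ceiling = 35),
                  base_filter_config(min_bmi_count = 1))
  for (cfg in relaxed) {
    expect_true(all(res$kept %in% apply_base_algorithm(co, cfg)$kept))
  }
})
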