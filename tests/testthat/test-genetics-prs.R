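w2 <- data.frame(variant_id = c("v1", "v2"), effect_allele = c("A", "G"),
                 weight = c(0.5, -1), stringsAsFactors = FALSE)

test_that("scores are dosage-weight dot products", {
  m <- matrix(c(2, 1), nrow = 1, dimnames = list("P1", c("v1", "v2")))
  expect_equal(compute_prs(m, w2)$raw_score, 0)
  zero <- w2; zero$weight <- 0
  m2 <- simulate_dosages(5, 2, seed = 3)
  colnames(m2) <- c("v1", "v2")
  expect_equal(compute_prs(m2, zero)$raw_score, rep(0, 5))
  expect_error(compute_prs(m, w2[0, ]), "empty weight")
  noverlap <- w2; noverlap$variant_id <- c("x1", "x2")
  expect_error(compute_prs(m, noverlap), "no overlap")
})

test_that("scores match the double-loop oracle, including mean imputation
           of missing dosages", {
  m <- simulate_dosages(50, 200, maf = runif(200, 0.05, 0.5),
                        missing_rate = 0.05, seed = 11)
  w <- data.frame(variant_id = colnames(m), effect_allele = "A",
                  weight = rnorm(200), stringsAsFactors = FALSE)
  got <- compute_prs(m, w)$raw_score
  expect_equal(got, oracle_prs(m, w), tolerance = 1e-12)
  # additivity over disjoint weight subsets
  s1 <- compute_prs(m, w[1:80, ])$raw_score
  s2 <- compute_prs(m, w[81:200, ])$raw_score
  expect_equal(s1 + s2, got, tolerance = 1e-12)
  # zero-contribution mode for missing cells
  gz <- compute_prs(m, w, missing = "zero")$raw_score
  mz <- m; mz[is.na(mz)] <- 0
  expect_equal(gz, as.numeric(mz %*% w$weight), tolerance = 1e-12)
})

test_that("the nonnegative shift anchors the minimum at zero, preserves
           ranks, and is idempotent", {
  m <- simulate_dosages(30, 10, seed = 7)
  w <- data.frame(variant_id = colnames(m), effect_allele = "A",
                  weight = rnorm(10), stringsAsFactors = FALSE)
  s <- shift_nonnegative(compute_prs(m, w))
  expect_equal(min(s$transformed_score), 0)
  expect_equal(rank(s$transformed_score), rank(s$raw_score))
  expect_equal(shift_nonnegative(s)$transformed_score,
               s$transformed_score)
  one <- compute_prs(m[1, , drop = FALSE], w)
  expect_equal(shift_nonnegative(one)$transformed_score, 0)
  expect_error(shift_nonnegative(one[0, ]), "empty")
})

test_that("centiles count the reference strictly below and are monotone", {
  mk <- function(raw) {
    data.frame(patient_id = as.character(seq_along(raw)),
               score_type = "T2D_gePS", raw_score = raw,
               transformed_score = NA_real_, centile = NA_integer_)
  }
  ref <- 1:100
  expect_equal(prs_centiles(mk(50.5), ref)$centile, 50L)
  expect_equal(prs_centiles(mk(0.5), ref)$centile, 0L)
  expect_equal(prs_centiles(mk(100), ref)$centile, 99L)
  expect_equal(prs_centiles(mk(101), ref)$centile, 100L)
  got <- prs_centiles(mk(sort(runif(20, 0, 101))), ref)$centile
  expect_true(all(diff(got) >= 0))
  expect_error(prs_centiles(mk(1), numeric(0)), "empty reference")
})

test_that("the HWE exact test matches the closed-form mass oracle", {
  set.seed(42)
  for (i in 1:30) {
    n <- sample(5:200, 1)
    f <- runif(1, 0.05, 0.5)
    g <- rbinom(n, 2, f)
    p_pkg <- hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
    p_ora <- oracle_hwe_p(sum(g == 0), sum(g == 1), sum(g == 2))
    expect_equal(p_pkg, p_ora, tolerance = 1e-10)
  }
  # equilibrium-consistent counts are not significant
  expect_gt(hwe_exact_test(25, 50, 25), 0.05)
})

test_that("variant QC drops on missingness, MAF, HWE and differential
           missingness with reason codes", {
  m <- simulate_dosages(200, 4, maf = c(0.3, 0.3, 0.3, 0.3), seed = 19)
  colnames(m) <- c("ok", "miss", "mono", "allhet")
  m[1:120, "miss"] <- NA                      # 60% missing
  m[, "mono"] <- 0                            # monomorphic
  m[, "allhet"] <- 1                          # every genotype heterozygous
  qc <- variant_qc(m)
  expect_true("ok" %in% qc$kept)
  expect_true(any(qc$dropped$variant_id == "miss" &
                    qc$dropped$reason == "missingness"))
  expect_true(any(qc$dropped$variant_id == "mono" &
                    qc$dropped$reason == "maf"))
  expect_true(any(qc$dropped$variant_id == "allhet" &
                    qc$dropped$reason == "hwe"))
  # differential missingness needs labels
  m2 <- simulate_dosages(200, 2, seed = 23)
  labels <- rep(c(TRUE, FALSE), each = 100)
  m2[1:30, 1] <- NA   # cases only: 30% vs 0%
  cfg <- variant_qc_config(max_missing_rate = 0.5)
  qc2 <- variant_qc(m2, labels, cfg)
  expect_true(any(qc2$dropped$reason == "differential_missingness"))
  expect_false("differential_missingness" %in%
                 variant_qc(m2, config = cfg)$dropped$reason)
  expect_error(variant_qc_config(max_missing_rate = 1.5), "\\[0, 1\\]")
})

test_that("weight and dosage tables round-trip through the readers", {
  d <- withr::local_tempdir()
  wf <- file.path(d, "weights.csv")
  utils::write.csv(w2, wf, row.names = FALSE)
  expect_equal(read_weights(wf)$weight, c(0.5, -1))
  m <- simulate_dosages(4, 2, seed = 5)
  colnames(m) <- c("v1", "v2")
  df <- data.frame(patient_id = rownames(m), m, check.names = FALSE)
  mf <- file.path(d, "dosages.csv")
  utils::write.csv(df, mf, row.names = FALSE)
  expect_equal(read_dosages(mf), m)
  # transposed layout
  tdf <- data.frame(variant_id = colnames(m), t(m), check.names = FALSE)
  tf <- file.path(d, "dosages_t.csv")
  utils::write.csv(tdf, tf, row.names = FALSE)
  expect_equal(read_dosages(tf, transposed = TRUE), m)
  dup <- rbind(w2, w2[1, ])
  utils::write.csv(dup, wf, row.names = FALSE)
  expect_error(read_weights(wf), "duplicate")
})
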