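test_that("median/IQR uses the linear-interpolation convention", {
  ages <- table2_cases()$current_age
  got <- median_iqr(ages)
  expect_equal(unname(got), c(69.5, 65.75, 76.25))
  expect_equal(unname(median_iqr(7)), c(7, 7, 7))
  expect_error(median_iqr(numeric(0)), "empty")
  set.seed(12)
  for (i in 1:25) {
    v <- round(rnorm(sample(2:40, 1), 50, 12), 2)
    got <- median_iqr(v)
    expect_equal(unname(got),
                 c(oracle_quantile(v, 0.5), oracle_quantile(v, 0.25),
                   oracle_quantile(v, 0.75)))
  }
})

test_that("exact rank-sum p-values equal full enumeration for pooled
           n <= 12, with and without ties", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12),
                                 mode = "exact")$p_value, 0.1)
  same <- c(4, 5, 6)
  expect_equal(wilcoxon_rank_sum(same, same, mode = "exact")$p_value, 1)
  set.seed(3)
  for (i in 1:40) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    pool <- sample(1:6, nx + ny, replace = TRUE)   # heavy ties
    x <- pool[seq_len(nx)]; y <- pool[-seq_len(nx)]
    expect_equal(wilcoxon_rank_sum(x, y, mode = "exact")$p_value,
                 oracle_wilcoxon_exact(x, y), tolerance = 1e-12,
                 info = sprintf("iter %d", i))
  }
})

test_that("the normal approximation agrees with the exact tail for small
           samples and with the standard implementation", {
  set.seed(8)
  for (i in 1:25) {
    x <- rnorm(sample(4:6, 1)); y <- rnorm(sample(4:6, 1), 0.5)
    pe <- wilcoxon_rank_sum(x, y, mode = "exact")$p_value
    pa <- wilcoxon_rank_sum(x, y, mode = "approx")$p_value
    expect_lt(abs(pe - pa), 0.05)
  }
  for (i in 1:25) {
    x <- round(rnorm(15, 0, 2), 1); y <- round(rnorm(20, 1, 2), 1)
    got <- wilcoxon_rank_sum(x, y, mode = "approx")
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "empty")
})

test_that("rank tests are invariant to within-group permutation", {
  set.seed(31)
  x <- rnorm(10); y <- rnorm(12)
  a <- wilcoxon_rank_sum(x, y)
  b <- wilcoxon_rank_sum(sample(x), sample(y))
  expect_identical(a, b)
  g <- list(rnorm(6), rnorm(7), rnorm(5))
  expect_equal(kruskal_wallis(g),
               kruskal_wallis(lapply(g, sample)))
})

test_that("Kruskal-Wallis handles degenerate ties and matches the
           squared-normal-deviate identity for two tie-free groups", {
  expect_equal(kruskal_wallis(list(c(3, 3, 3), c(3, 3)))$statistic, 0)
  expect_error(kruskal_wallis(list(1:3)), "two nonempty")
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(9); y <- rnorm(11)   # continuous: no ties
    H <- kruskal_wallis(list(x, y))$statistic
    u <- wilcoxon_rank_sum(x, y, mode = "approx")$statistic
    mu <- length(x) * length(y) / 2
    sigma2 <- length(x) * length(y) * (length(x) + length(y) + 1) / 12
    expect_equal(H, (u - mu)^2 / sigma2, tolerance = 1e-10)
  }
})

test_that("two-sided rank-sum p-values are not anticonservative under the
           null", {
  set.seed(2718)
  reps <- 1000
  rejections <- sum(vapply(seq_len(reps), function(i) {
    wilcoxon_rank_sum(rnorm(20), rnorm(20), mode = "approx")$p_value
  }, numeric(1)) < 0.05)
  # super-uniform at the 5% level within binomial error
  expect_lt(rejections, reps * 0.05 + 3 * sqrt(reps * 0.05 * 0.95))
})

test_that("group comparison detects planted shifts and enforces
           disjointness", {
  g <- generate_cohort(generator_config(
    3000, seed = 606, archetypes = default_archetypes(ad_prevalence = 0.01)))
  co <- g$cohort
  tr <- g$truth
  ad <- tr$patient_id[grepl("^AD_", tr$archetype)]
  t1d <- tr$patient_id[tr$archetype == "typical_T1D"]
  t2d <- tr$patient_id[tr$archetype == "typical_T2D"]
  tab <- compare_groups(co, ad, t1d, t2d)
  # construction: atypical cases have higher HDL and lower BMI than T2D
  hdl <- tab[tab$variable == "hdl", ]
  expect_gt(hdl$ad_median, hdl$t2d_median)
  expect_lt(hdl$p_ad_vs_t2d, 0.05)
  bmi <- tab[tab$variable == "bmi", ]
  expect_lt(bmi$ad_median, bmi$t2d_median)
  # categorical variable routed to the rank test
  expect_equal(tab$test[tab$variable == "sex"], "kruskal_wallis")
  expect_equal(tab$test[tab$variable == "age"], "wilcoxon_rank_sum")
  # overlapping groups are a caller error
  expect_error(compare_groups(co, ad, c(t1d, ad[1]), t2d), "disjoint")
  expect_error(compare_groups(co, c("ZZZ", ad), t1d, t2d), "unknown id")
  # fisher alternative for the categorical route
  tabf <- compare_groups(co, ad, t1d, t2d, variables = "sex",
                         categorical_test = "fisher")
  expect_equal(tabf$test, "fisher_exact")
})
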