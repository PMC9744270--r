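# Descriptive statistics and nonparametric group comparisons for the
# atypical vs ML-phenotype cohort tables: median/IQR summaries, the
# Wilcoxon rank-sum test (normal approximation with tie and continuity
# corrections, plus an exact small-sample mode), and the Kruskal-Wallis
# rank test.

#' Median and interquartile range
#'
#' Quantiles use the linear-interpolation convention at positions
#' `1 + (n - 1) p` (R's default, quantile type 7) — the convention under
#' which the published cohort summaries reproduce exactly.
#'
#' @param values nonempty numeric vector (NAs dropped).
#' @return named numeric vector `c(median, q1, q3)`.
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("empty input")
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test with midrank ties. The reported statistic is
#' the Mann-Whitney U of the first sample (rank sum minus its minimum).
#' In `"approx"` mode the p-value uses the normal approximation with the
#' tie-corrected variance and a 0.5 continuity correction; in `"exact"`
#' mode the full conditional distribution of the rank sum given the
#' pooled (midrank) ranks is computed by a shift-algorithm convolution,
#' and the two-sided p doubles the smaller tail (capped at 1). `"auto"`
#' uses the exact mode when the pooled sample size is at most 12.
#'
#' @param x,y nonempty numeric vectors.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return list: `statistic` (U), `p_value`, `mode` used.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) stop("empty group")
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (mode == "auto") mode <- if (n <= 12) "exact" else "approx"
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  u <- w - nx * (nx + 1) / 2
  if (mode == "exact") {
    p <- exact_ranksum_p(r, nx, w)
  } else {
    mu <- nx * ny / 2
    ties <- table(r)
    sigma2 <- nx * ny / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      cc <- min(0.5, abs(u - mu))   # continuity correction toward the mean
      z <- (abs(u - mu) - cc) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-z))
    }
  }
  list(statistic = u, p_value = p, mode = mode)
}

# conditional null distribution of the rank sum of the first sample given
# the pooled midranks: dynamic programming over items, tracking (number
# chosen, doubled rank sum); midranks are half-integers so doubling makes
# the support integral
exact_ranksum_p <- function(r, nx, w) {
  r2 <- as.integer(round(2 * r))
  n <- length(r2)
  smax <- sum(r2)
  counts <- matrix(0, nrow = nx + 1, ncol = smax + 1)
  counts[1, 1] <- 1   # zero items chosen, sum zero
  for (item in r2) {
    for (k in nx:1) {
      counts[k + 1, ] <- counts[k + 1, ] + shift_vec(counts[k, ], item)
    }
  }
  dist <- counts[nx + 1, ]
  total <- sum(dist)
  w2 <- as.integer(round(2 * w))
  p_le <- sum(dist[seq_len(w2 + 1)]) / total
  p_ge <- sum(dist[(w2 + 1):(smax + 1)]) / total
  min(1, 2 * min(p_le, p_ge))
}

shift_vec <- function(v, by) {
  out <- numeric(length(v))
  if (by < length(v)) out[(by + 1):length(v)] <- v[1:(length(v) - by)]
  out
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic referred to a chi-square distribution with
#' k - 1 degrees of freedom (delegates to [stats::kruskal.test()]).
#'
#' @param groups list of at least two nonempty numeric vectors.
#' @return list: `statistic` (H), `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    stop("need at least two nonempty groups")
  }
  if (length(unique(unlist(groups))) == 1) {
    # fully tied data carry no rank information: H = 0 by convention
    return(list(statistic = 0, p_value = 1, df = length(groups) - 1))
  }
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

COMPARE_VARIABLES <- c("age", "bmi", "hba1c", "hdl", "tg", "sex")

#' Compare the atypical group with the ML phenotype groups
#'
#' Builds the standard comparison table: per-variable most-recent value
#' extraction, per-group median/IQR, and pairwise atypical-vs-ML-T1D and
#' atypical-vs-ML-T2D tests — Wilcoxon rank-sum for continuous
#' variables, the rank test on integer-coded categories for categorical
#' ones (as is conventional in this literature; `categorical_test =
#' "fisher"` switches to Fisher's exact test). P-values are not adjusted
#' for multiple testing (`p_adjust = "none"`), matching the descriptive,
#' hypothesis-generating use of the table.
#'
#' @param x an `"adscreen_cohort"`.
#' @param ad_ids,t1d_ids,t2d_ids disjoint id sets; the ML groups must
#'   already exclude algorithm-identified candidates (overlap is an
#'   error).
#' @param variables subset of `age`, `bmi`, `hba1c`, `hdl`, `tg`, `sex`.
#' @param exact force exact rank-test mode for the pairwise tests.
#' @param categorical_test `"rank"` or `"fisher"`.
#' @param p_adjust a [stats::p.adjust()] method, default `"none"`.
#' @return data.frame, one row per variable: group sizes, median/IQR per
#'   group, test names and the two pairwise p-values.
#' @export
compare_groups <- function(x, ad_ids, t1d_ids, t2d_ids,
                           variables = COMPARE_VARIABLES, exact = FALSE,
                           categorical_test = c("rank", "fisher"),
                           p_adjust = "none") {
  categorical_test <- match.arg(categorical_test)
  validate_cohort(x)
  groups <- list(ad = ad_ids, t1d = t1d_ids, t2d = t2d_ids)
  if (length(unique(unlist(groups))) != length(unlist(groups))) {
    stop("groups must be disjoint ",
         "(remove algorithm-identified patients from the ML groups)")
  }
  unknown <- setdiff(unlist(groups), x$patients$patient_id)
  if (length(unknown) > 0) {
    stop("unknown id(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  variables <- match.arg(variables, COMPARE_VARIABLES, several.ok = TRUE)
  vals <- extract_variables(x, unlist(groups), variables)
  mode <- if (exact) "exact" else "auto"
  rows <- lapply(variables, function(v) {
    gv <- lapply(groups, function(ids) {
      out <- vals[[v]][match(ids, names(vals[[v]]))]
      out[!is.na(out)]
    })
    summ <- lapply(gv, function(g) {
      if (length(g) == 0) c(median = NA_real_, q1 = NA_real_,
                            q3 = NA_real_) else median_iqr(g)
    })
    if (v == "sex" && categorical_test == "fisher") {
      test_name <- "fisher_exact"
      pair_p <- function(a, b) {
        stats::fisher.test(table(c(rep("ad", length(a)),
                                   rep("ml", length(b))),
                                 c(a, b)))$p.value
      }
    } else if (v == "sex") {
      test_name <- "kruskal_wallis"
      pair_p <- function(a, b) kruskal_wallis(list(a, b))$p_value
    } else {
      test_name <- "wilcoxon_rank_sum"
      pair_p <- function(a, b) wilcoxon_rank_sum(a, b, mode)$p_value
    }
    data.frame(
      variable = v,
      n_ad = length(gv$ad), n_t1d = length(gv$t1d), n_t2d = length(gv$t2d),
      ad_median = summ$ad[["median"]], ad_q1 = summ$ad[["q1"]],
      ad_q3 = summ$ad[["q3"]],
      t1d_median = summ$t1d[["median"]], t1d_q1 = summ$t1d[["q1"]],
      t1d_q3 = summ$t1d[["q3"]],
      t2d_median = summ$t2d[["median"]], t2d_q1 = summ$t2d[["q1"]],
      t2d_q3 = summ$t2d[["q3"]],
      test = test_name,
      p_ad_vs_t1d = pair_p(gv$ad, gv$t1d),
      p_ad_vs_t2d = pair_p(gv$ad, gv$t2d),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_ad_vs_t1d <- stats::p.adjust(out$p_ad_vs_t1d, method = p_adjust)
  out$p_ad_vs_t2d <- stats::p.adjust(out$p_ad_vs_t2d, method = p_adjust)
  out
}

# named per-patient values for the comparison variables; "most recent"
# extraction for the longitudinal ones
extract_variables <- function(x, ids, variables) {
  ids <- as.character(ids)
  ref_year <- if (nrow(x$labs) > 0 || nrow(x$bmi) > 0) {
    as.integer(format(max(c(x$labs$date, x$bmi$date)), "%Y"))
  } else NA_integer_
  out <- list()
  if ("age" %in% variables) {
    by <- x$patients$birth_year[match(ids, x$patients$patient_id)]
    out$age <- stats::setNames(ref_year - by, ids)
  }
  if ("sex" %in% variables) {
    sx <- x$patients$sex[match(ids, x$patients$patient_id)]
    out$sex <- stats::setNames(as.numeric(factor(sx,
                                                 levels = SEX_LEVELS)), ids)
  }
  if ("bmi" %in% variables) {
    sub <- x$bmi[x$bmi$patient_id %in% ids, , drop = FALSE]
    recent <- vapply(split(sub, sub$patient_id),
                     function(d) most_recent(d)$value, numeric(1))
    out$bmi <- stats::setNames(recent[match(ids, names(recent))], ids)
  }
  lab_map <- c(hba1c = "HbA1c", hdl = "HDL", tg = "TG")
  for (v in intersect(variables, names(lab_map))) {
    sub <- x$labs[x$labs$patient_id %in% ids &
                    x$labs$analyte == lab_map[[v]], , drop = FALSE]
    recent <- vapply(split(sub, sub$patient_id),
                     function(d) most_recent(d)$value, numeric(1))
    out[[v]] <- stats::setNames(recent[match(ids, names(recent))], ids)
  }
  out
}
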