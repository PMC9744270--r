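# Polygenic score computation from allele dosages, the nonnegative shift
# transform for the T2D global extended score, reference centiles, and
# per-variant quality-control filters.

#' Read a variant-weight table
#'
#' Three-column delimited layout with header: `variant_id`,
#' `effect_allele`, `weight`.
#'
#' @param path file path.
#' @return data.frame with unique `variant_id`s.
#' @export
read_weights <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "effect_allele", "weight")
  if (!all(need %in% names(w))) {
    stop("weight table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(w$variant_id)) stop("duplicate variant_id in weights")
  w$weight <- as.numeric(w$weight)
  w[need]
}

#' Read a dosage matrix
#'
#' Delimited text with a `patient_id` column and one numeric column per
#' variant holding effect-allele dosages in [0, 2] (missing cells empty
#' or NA). With `transposed = TRUE` the file is variants-by-patients
#' (`variant_id` column, one column per patient).
#'
#' @param path file path.
#' @param transposed whether the file is variants-by-patients.
#' @return numeric matrix, patients in rows (rownames = patient ids),
#'   variants in columns.
#' @export
read_dosages <- function(path, transposed = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  key <- if (transposed) "variant_id" else "patient_id"
  if (!key %in% names(df)) stop("dosage table must have column ", key)
  m <- as.matrix(df[setdiff(names(df), key)])
  storage.mode(m) <- "double"
  rownames(m) <- df[[key]]
  if (transposed) m <- t(m)
  validate_dosages(m)
  m
}

validate_dosages <- function(m) {
  if (any(!is.na(m) & (m < 0 | m > 2))) {
    stop("dosages must lie in [0, 2]")
  }
  invisible(m)
}

#' Compute polygenic scores from dosages and weights
#'
#' The raw score of a patient is the sum over variants of effect-allele
#' dosage times per-allele weight. Missing dosage cells contribute the
#' cohort-mean dosage of that variant (`missing = "mean"`, the standard
#' scoring behaviour) or nothing (`missing = "zero"`).
#'
#' @param dosages patients-by-variants matrix (see [read_dosages()]).
#' @param weights data.frame from [read_weights()].
#' @param score_type `"T1D_rsPS"` or `"T2D_gePS"` (a tag carried in the
#'   result).
#' @param missing how missing dosages contribute.
#' @return data.frame of class `"prs_result"`: `patient_id`,
#'   `score_type`, `raw_score`, `transformed_score` (NA until
#'   [shift_nonnegative()]), `centile` (NA until [prs_centiles()]).
#' @export
compute_prs <- function(dosages, weights,
                        score_type = c("T2D_gePS", "T1D_rsPS"),
                        missing = c("mean", "zero")) {
  score_type <- match.arg(score_type)
  missing <- match.arg(missing)
  if (nrow(weights) == 0) stop("empty weight list")
  validate_dosages(dosages)
  overlap <- intersect(weights$variant_id, colnames(dosages))
  if (length(overlap) == 0) {
    stop("no overlap between weight variants and dosage columns")
  }
  m <- dosages[, overlap, drop = FALSE]
  w <- weights$weight[match(overlap, weights$variant_id)]
  if (missing == "mean") {
    mu <- colMeans(m, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(m), arr.ind = TRUE)
    if (nrow(idx) > 0) m[idx] <- mu[idx[, 2]]
  } else {
    m[is.na(m)] <- 0
  }
  raw <- as.numeric(m %*% w)
  out <- data.frame(patient_id = rownames(dosages),
                    score_type = score_type, raw_score = raw,
                    transformed_score = NA_real_, centile = NA_integer_,
                    stringsAsFactors = FALSE)
  class(out) <- c("prs_result", "data.frame")
  out
}

#' Shift scores into the nonnegative range
#'
#' Linear transform setting the minimum raw score to exactly 0 (used for
#' the T2D global extended score, for interpretability). Rank order is
#' preserved; applying the shift to already shifted scores is a no-op.
#'
#' @param scores a `"prs_result"` data.frame.
#' @return the input with `transformed_score` filled.
#' @export
shift_nonnegative <- function(scores) {
  if (nrow(scores) == 0) stop("empty score list")
  base <- if (all(!is.na(scores$transformed_score))) {
    scores$transformed_score
  } else {
    scores$raw_score
  }
  scores$transformed_score <- base - min(base)
  scores
}

#' Attach reference centiles to scores
#'
#' The centile of a score is `round(100 * f)` where `f` is the fraction
#' of the reference distribution strictly below the score. Ties with
#' reference values therefore do not count as "below": a score equal to
#' the reference minimum gets centile 0, and a score equal to the
#' reference maximum of an n-value reference gets
#' `round(100 (n-1) / n)` (99 for n = 100; 100 only when it strictly
#' exceeds every reference value).
#'
#' @param scores a `"prs_result"` data.frame.
#' @param reference_scores numeric vector of reference raw scores.
#' @return the input with `centile` filled.
#' @export
prs_centiles <- function(scores, reference_scores) {
  if (length(reference_scores) == 0) stop("empty reference")
  scores$centile <- vapply(scores$raw_score, function(s) {
    as.integer(round(100 * mean(reference_scores < s)))
  }, integer(1))
  scores
}

#' Variant quality-control configuration
#'
#' Thresholds for per-variant filters: call-rate, minor allele
#' frequency, Hardy-Weinberg equilibrium and case/control differential
#' missingness. The source pipeline states these filters without
#' numeric thresholds; the defaults here are conventional GWAS-QC
#' values, surfaced in configuration.
#'
#' @param max_missing_rate drop variants missing in more than this
#'   fraction of patients (default 0.05).
#' @param hwe_p_floor drop variants whose HWE exact-test p-value falls
#'   below this (default 1e-6).
#' @param maf_floor drop variants with minor allele frequency below this
#'   (default 0.01).
#' @param max_differential_missingness drop variants whose case vs
#'   control missingness differs by more than this (default 0.02);
#'   checked only when labels are supplied.
#' @return list of class `"variant_qc_config"`.
#' @export
variant_qc_config <- function(max_missing_rate = 0.05, hwe_p_floor = 1e-6,
                              maf_floor = 0.01,
                              max_differential_missingness = 0.02) {
  vals <- c(max_missing_rate, hwe_p_floor, maf_floor,
            max_differential_missingness)
  if (any(vals < 0 | vals > 1)) stop("QC thresholds must lie in [0, 1]")
  structure(list(max_missing_rate = max_missing_rate,
                 hwe_p_floor = hwe_p_floor, maf_floor = maf_floor,
                 max_differential_missingness =
                   max_differential_missingness),
            class = "variant_qc_config")
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Exact conditional test on genotype counts: conditional on the observed
#' allele counts, the probability of each possible heterozygote count is
#' computed in closed form and the p-value is the total probability of
#' outcomes no more likely than the observed one (the usual two-sided
#' exact HWE convention). Robust at small sample sizes where the
#' chi-square test is not.
#'
#' @param n_aa,n_ab,n_bb genotype counts (major homozygote, heterozygote,
#'   minor homozygote — orientation does not matter).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab   # allele A count
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  # possible heterozygote counts share the parity of the rare allele count
  het <- seq(rare %% 2, rare, by = 2)
  # log P(het | allele counts) up to a common constant
  logp <- het * log(2) - lfactorial((n_a - het) / 2) -
    lfactorial(het) - lfactorial((n_b - het) / 2)
  logp <- logp - max(logp)
  p <- exp(logp) / sum(exp(logp))
  obs <- match(n_ab, het)
  if (is.na(obs)) stop("inconsistent genotype counts")
  sum(p[p <= p[obs] + 1e-12])
}

#' Per-variant quality control
#'
#' Applies the four filters of [variant_qc_config()] to a dosage matrix.
#' For the MAF and HWE checks, dosages are hard-called by rounding to the
#' nearest integer genotype (the exact HWE test needs counts); scoring
#' itself keeps the fractional dosages.
#'
#' @param dosages patients-by-variants dosage matrix.
#' @param case_control_labels optional logical/0-1 vector over patients
#'   (TRUE = case) enabling the differential-missingness check.
#' @param config a [variant_qc_config()].
#' @return list with `kept` (variant ids) and `dropped` (data.frame
#'   `variant_id` / `reason`; a variant failing several filters is
#'   reported once per reason).
#' @export
variant_qc <- function(dosages, case_control_labels = NULL,
                       config = variant_qc_config()) {
  validate_dosages(dosages)
  if (!is.null(case_control_labels)) {
    stopifnot(length(case_control_labels) == nrow(dosages))
    case_control_labels <- as.logical(case_control_labels)
  }
  reasons <- list()
  for (v in colnames(dosages)) {
    col <- dosages[, v]
    why <- character(0)
    miss_rate <- mean(is.na(col))
    if (miss_rate > config$max_missing_rate) why <- c(why, "missingness")
    g <- round(col[!is.na(col)])
    if (length(g) == 0) {
      why <- unique(c(why, "missingness"))
    } else {
      freq <- mean(g) / 2
      maf <- min(freq, 1 - freq)
      if (maf < config$maf_floor) why <- c(why, "maf")
      p_hwe <- hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
      if (p_hwe < config$hwe_p_floor) why <- c(why, "hwe")
    }
    if (!is.null(case_control_labels)) {
      dm <- abs(mean(is.na(col[case_control_labels])) -
                  mean(is.na(col[!case_control_labels])))
      if (!is.na(dm) && dm > config$max_differential_missingness) {
        why <- c(why, "differential_missingness")
      }
    }
    if (length(why) > 0) {
      reasons[[v]] <- data.frame(variant_id = v, reason = why,
                                 stringsAsFactors = FALSE)
    }
  }
  dropped <- if (length(reasons) > 0) {
    do.call(rbind, unname(reasons))
  } else {
    data.frame(variant_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  }
  list(kept = setdiff(colnames(dosages), dropped$variant_id),
       dropped = dropped)
}

#' Simulate a toy dosage matrix
#'
#' Hardy-Weinberg genotype draws at given allele frequencies with
#' independent missingness — a convenience for testing and examples, not
#' a population-genetic simulator.
#'
#' @param n_patients,n_variants matrix dimensions.
#' @param maf scalar or per-variant vector of allele frequencies.
#' @param missing_rate per-cell missingness probability.
#' @param seed integer seed.
#' @return dosage matrix with patient/variant dimnames.
#' @export
simulate_dosages <- function(n_patients, n_variants, maf = 0.3,
                             missing_rate = 0, seed = 1) {
  maf <- rep_len(maf, n_variants)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  m <- vapply(maf, function(f) {
    stats::rbinom(n_patients, 2, f)
  }, numeric(n_patients))
  m <- matrix(as.double(m), nrow = n_patients,
              dimnames = list(sprintf("P%04d", seq_len(n_patients)),
                              sprintf("rs%05d", seq_len(n_variants))))
  if (missing_rate > 0) {
    m[stats::runif(length(m)) < missing_rate] <- NA
  }
  m
}
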