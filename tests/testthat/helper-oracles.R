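# Independent reference implementations ("oracles") kept deliberately
# different in style from the package code: set-based flat scans instead of
# per-patient predicates, full enumeration instead of convolution, direct
# probability mass instead of recurrences.

# base algorithm as flat set algebra over the entity tables
oracle_base_kept <- function(co, cfg = base_filter_config()) {
  input <- co$ml_flags$patient_id[co$ml_flags$ml_t2d %in% TRUE]
  labs <- co$labs; bmi <- co$bmi
  ex_hdl <- labs$patient_id[labs$analyte == "HDL" &
                              labs$value < cfg$hdl_floor]
  ex_tg <- labs$patient_id[labs$analyte == "TG" &
                             labs$value > cfg$tg_ceiling]
  ex_bmi <- bmi$patient_id[bmi$value > cfg$bmi_ceiling]
  ok <- bmi$value >= cfg$bmi_normal_floor &
    bmi$value <= cfg$bmi_normal_ceiling
  counts <- table(bmi$patient_id[ok])
  engaged <- names(counts)[counts >= cfg$min_bmi_count]
  ex_eng <- setdiff(input, engaged)
  pat <- paste0("^(", paste(gsub("\\.", "\\\\.", cfg$cf_code_set),
                            collapse = "|"), ")")
  ex_cf <- co$diagnoses$patient_id[grepl(pat, co$diagnoses$code)]
  ex_ab <- co$antibodies$patient_id[co$antibodies$result == "positive" &
                                      co$antibodies$antibody %in%
                                        cfg$antibody_panel]
  sort(setdiff(input, c(ex_hdl, ex_tg, ex_bmi, ex_eng, ex_cf, ex_ab)))
}

# branch union as flat set algebra
oracle_branch_union <- function(co, base_kept) {
  m <- co$medications; ab <- co$antibodies; fl <- co$ml_flags
  neg_doc <- setdiff(ab$patient_id[ab$result == "negative"],
                     ab$patient_id[ab$result == "positive"])
  b1 <- intersect(base_kept, neg_doc)
  out_insulin <- m$patient_id[m$drug_class == "insulin" &
                                m$setting == "outpatient"]
  b2 <- setdiff(base_kept, out_insulin)
  t2d_med <- m$patient_id[m$drug_class %in% T2D_SPECIFIC_CLASSES]
  b3 <- intersect(base_kept, t2d_med)
  b4 <- intersect(base_kept,
                  c(t2d_med, m$patient_id[m$drug_class == "metformin"]))
  b5 <- intersect(base_kept,
                  fl$patient_id[fl$ml_t1d_ruled_out %in% TRUE])
  b6 <- setdiff(base_kept, fl$patient_id[fl$ml_t1d_high_ppv %in% TRUE])
  sort(unique(c(b1, b2, b3, b4, b5, b6)))
}

# exact two-sided rank-sum p by enumerating every assignment of group
# labels to the pooled midranks
oracle_wilcoxon_exact <- function(x, y) {
  r <- rank(c(x, y))
  nx <- length(x)
  w <- sum(r[seq_len(nx)])
  sums <- apply(utils::combn(length(r), nx), 2,
                function(idx) sum(r[idx]))
  p_le <- mean(sums <= w + 1e-9)
  p_ge <- mean(sums >= w - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# HWE exact p from the closed-form conditional probability of each
# heterozygote count (no recurrence, explicit normalising constant)
oracle_hwe_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  hets <- seq(min(n_a, n_b) %% 2, min(n_a, n_b), by = 2)
  lmass <- vapply(hets, function(h) {
    lfactorial(n) - lfactorial((n_a - h) / 2) - lfactorial(h) -
      lfactorial((n_b - h) / 2) + h * log(2) +
      lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  }, numeric(1))
  mass <- exp(lmass)
  obs <- mass[hets == n_ab]
  sum(mass[mass <= obs + 1e-12]) / sum(mass)
}

# quantiles by explicit sort-and-interpolate at h = 1 + (n-1) p
oracle_quantile <- function(v, p) {
  v <- sort(v)
  h <- 1 + (length(v) - 1) * p
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# PRS as an explicit double loop with mean imputation
oracle_prs <- function(dosages, weights) {
  mu <- apply(dosages, 2, function(c) {
    m <- mean(c, na.rm = TRUE)
    if (is.nan(m)) 0 else m
  })
  out <- numeric(nrow(dosages))
  for (i in seq_len(nrow(dosages))) {
    s <- 0
    for (j in seq_len(nrow(weights))) {
      v <- weights$variant_id[j]
      d <- dosages[i, v]
      if (is.na(d)) d <- mu[[v]]
      s <- s + d * weights$weight[j]
    }
    out[i] <- s
  }
  out
}
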