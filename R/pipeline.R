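# End-to-end orchestration: simulate (or load) -> base algorithm ->
# branch algorithms -> candidate union -> chart classification ->
# subtype assignment -> attrition and yield reporting.

#' Run the full screening pipeline
#'
#' Takes either a cohort or a generator configuration (in which case the
#' cohort is simulated first), applies the base algorithm to the
#' ML-flagged T2D group, runs the six branch algorithms over the base
#' survivors, assembles the candidate union, classifies every candidate
#' with the chart-review rule engine, and reports stage-by-stage
#' attrition and per-branch yields. Deterministic: the same input and
#' configuration always produce the same report.
#'
#' @param x an `"adscreen_cohort"` or a [generator_config()].
#' @param base_config a [base_filter_config()].
#' @param rules a `"classifier_rules"` list.
#' @param config a [subtype_config()].
#' @param output_dir optional directory; when given, the candidate
#'   membership table, per-patient outcomes, attrition table, yield table
#'   and a run manifest are written there as delimited text/JSON.
#' @return list of class `"ad_pipeline_result"`: `cohort`, `truth` (NULL
#'   unless simulated), `base` (a `"filter_result"`), `branches`,
#'   `candidates` (a `"candidate_set"`), `classification` (a
#'   `"cohort_classification"`), `attrition` (data.frame stage / n_in /
#'   n_excluded / n_out) and `yields` (data.frame, per branch plus an
#'   overall row).
#' @export
run_pipeline <- function(x, base_config = base_filter_config(),
                         rules = default_classifier_rules(),
                         config = subtype_config(), output_dir = NULL) {
  truth <- NULL
  if (inherits(x, "generator_config")) {
    gen <- generate_cohort(x)
    truth <- gen$truth
    x <- gen$cohort
  }
  stopifnot(inherits(x, "adscreen_cohort"))
  base <- apply_base_algorithm(x, base_config)
  branches <- run_branches(x, base$kept)
  candidates <- assemble_candidates(branches)
  classification <- classify_cohort(candidates, x, rules, config)
  attrition <- rbind(
    data.frame(stage = "ml_t2d_group", n_in = n_patients(x),
               n_excluded = n_patients(x) - base$input_size,
               n_out = base$input_size, stringsAsFactors = FALSE),
    data.frame(stage = paste0("base_", base$attrition$criterion),
               n_in = c(base$input_size,
                        utils::head(base$attrition$n_remaining, -1)),
               n_excluded = base$attrition$n_excluded,
               n_out = base$attrition$n_remaining,
               stringsAsFactors = FALSE),
    data.frame(stage = "branch_union", n_in = length(base$kept),
               n_excluded = length(base$kept) -
                 length(candidates$union_ids),
               n_out = length(candidates$union_ids),
               stringsAsFactors = FALSE))
  yields <- yield_summary(candidates, classification$outcomes)
  out <- structure(list(cohort = x, truth = truth, base = base,
                        branches = branches, candidates = candidates,
                        classification = classification,
                        attrition = attrition, yields = yields),
                   class = "ad_pipeline_result")
  if (!is.null(output_dir)) write_pipeline_outputs(out, output_dir)
  out
}

#' Per-branch and overall yield of confirmed atypical cases
#'
#' Yield of a branch is the number of its kept patients classified
#' atypical divided by the number kept (NA for an empty branch); the
#' overall row uses the candidate union.
#'
#' @param candidates a `"candidate_set"`.
#' @param outcomes outcomes data.frame from [classify_cohort()] (columns
#'   `patient_id`, `category`) covering all candidates.
#' @return data.frame: `branch`, `n_kept`, `n_ad`, `yield`.
#' @export
yield_summary <- function(candidates, outcomes) {
  if (!all(candidates$union_ids %in% outcomes$patient_id)) {
    stop("outcomes do not cover all candidates")
  }
  ad_ids <- outcomes$patient_id[outcomes$category == "AD"]
  m <- candidates$membership
  rows <- lapply(seq_len(ncol(m)), function(b) {
    kept <- rownames(m)[m[, b]]
    data.frame(branch = colnames(m)[b], n_kept = length(kept),
               n_ad = length(intersect(kept, ad_ids)),
               yield = if (length(kept) > 0) {
                 length(intersect(kept, ad_ids)) / length(kept)
               } else NA_real_,
               stringsAsFactors = FALSE)
  })
  union_n <- length(candidates$union_ids)
  rbind(do.call(rbind, rows),
        data.frame(branch = "overall", n_kept = union_n,
                   n_ad = length(intersect(candidates$union_ids, ad_ids)),
                   yield = if (union_n > 0) {
                     length(intersect(candidates$union_ids, ad_ids)) /
                       union_n
                   } else NA_real_,
                   stringsAsFactors = FALSE))
}

write_pipeline_outputs <- function(res, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) stop("output dir not writable: ", output_dir)
  m <- res$candidates$membership
  cand <- data.frame(patient_id = rownames(m), m, row.names = NULL,
                     check.names = FALSE)
  cand$n_branches <- rowSums(m)
  utils::write.csv(cand, file.path(output_dir, "candidates.csv"),
                   row.names = FALSE)
  utils::write.csv(res$classification$outcomes,
                   file.path(output_dir, "outcomes.csv"),
                   row.names = FALSE)
  utils::write.csv(res$attrition, file.path(output_dir, "attrition.csv"),
                   row.names = FALSE)
  utils::write.csv(res$yields, file.path(output_dir, "yields.csv"),
                   row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("adscreen")),
    cohort_provenance = res$cohort$provenance,
    cohort_seed = if (is.na(res$cohort$seed)) NULL else res$cohort$seed,
    n_patients = n_patients(res$cohort),
    n_candidates = length(res$candidates$union_ids))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(output_dir)
}

#' @export
print.ad_pipeline_result <- function(x, ...) {
  cat("<ad_pipeline_result>\n")
  print(x$attrition, row.names = FALSE)
  cat("\nYields:\n")
  y <- x$yields
  y$yield <- ifelse(is.na(y$yield), NA,
                    sprintf("%.1f%%", 100 * y$yield))
  print(y, row.names = FALSE)
  invisible(x)
}
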