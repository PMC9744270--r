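# Six branch algorithms: alternative rules for removing likely T1D from the
# base-algorithm survivors. Each branch is an independent predicate over the
# same input set, yielding six overlapping candidate cohorts whose union
# (with a per-branch membership matrix) goes to chart review.

# evaluate a per-patient predicate over an id set and wrap the result
eval_branch <- function(branch_id, ids, pred) {
  ids <- sort(ids)
  keep <- stats::setNames(vapply(ids, pred, logical(1)), ids)
  structure(list(branch_id = branch_id, kept = ids[keep],
                 excluded = ids[!keep]),
            class = "branch_result")
}

#' @export
print.branch_result <- function(x, ...) {
  cat(sprintf("<branch_result %d> kept %d / excluded %d\n", x$branch_id,
              length(x$kept), length(x$excluded)))
  invisible(x)
}

#' Branch 1: documented negative antibody testing
#'
#' Keeps patients with at least one islet autoantibody test on record, all
#' negative; untested patients are excluded because they could carry
#' unreported positive antibodies. (Positive-result patients cannot reach
#' this stage: the base algorithm removed them.)
#'
#' @param x an `"adscreen_cohort"`.
#' @param ids input patient ids (the base-algorithm kept set).
#' @param require_full_panel if `TRUE`, all three antibodies (GAD65, IA2,
#'   ZnT8) must have a documented negative result; default `FALSE` (any
#'   one negative test suffices, provided none is positive).
#' @return a `"branch_result"`.
#' @export
branch_1_documented_negative_antibodies <- function(x, ids,
                                                    require_full_panel = FALSE) {
  ab <- split(x$antibodies, x$antibodies$patient_id)
  eval_branch(1L, ids, function(id) {
    t <- ab[[id]]
    if (is.null(t) || nrow(t) == 0) return(FALSE)
    if (any(t$result == "positive")) return(FALSE)
    if (require_full_panel) {
      all(ANTIBODY_PANEL %in% t$antibody[t$result == "negative"])
    } else {
      any(t$result == "negative")
    }
  })
}

#' Branch 2: never used insulin in the outpatient setting
#'
#' @inheritParams branch_1_documented_negative_antibodies
#' @param cutoff_date optional `Date`; medication exposures after it are
#'   ignored (era control for drug-class repurposing). Default `NULL`.
#' @return a `"branch_result"`.
#' @export
branch_2_no_outpatient_insulin <- function(x, ids, cutoff_date = NULL) {
  meds <- med_split(x, cutoff_date)
  eval_branch(2L, ids, function(id) {
    m <- meds[[id]]
    if (is.null(m)) return(TRUE)
    !any(m$drug_class == "insulin" & m$setting == "outpatient")
  })
}

#' Branch 3: ever received a T2D-specific medication
#'
#' Keeps patients with at least one exposure in
#' [T2D_SPECIFIC_CLASSES] (sulfonylurea, meglitinide, TZD, DPP4i, AGI,
#' GLP-1 RA, SGLT2i). Metformin does not qualify.
#'
#' @inheritParams branch_2_no_outpatient_insulin
#' @return a `"branch_result"`.
#' @export
branch_3_t2d_specific_med <- function(x, ids, cutoff_date = NULL) {
  meds <- med_split(x, cutoff_date)
  eval_branch(3L, ids, function(id) {
    m <- meds[[id]]
    !is.null(m) && any(m$drug_class %in% T2D_SPECIFIC_CLASSES)
  })
}

#' Branch 4: ever received a T2D-specific medication or metformin
#'
#' A superset of branch 3 by construction.
#'
#' @inheritParams branch_2_no_outpatient_insulin
#' @return a `"branch_result"`.
#' @export
branch_4_t2d_med_or_metformin <- function(x, ids, cutoff_date = NULL) {
  meds <- med_split(x, cutoff_date)
  eval_branch(4L, ids, function(id) {
    m <- meds[[id]]
    !is.null(m) &&
      any(m$drug_class %in% c(T2D_SPECIFIC_CLASSES, "metformin"))
  })
}

#' Branch 5: T1D ruled out by the high-NPV phenotype flag
#'
#' Keeps patients whose `ml_t1d_ruled_out` flag (NPV 0.99 against chart
#' review) is `TRUE`.
#'
#' @inheritParams branch_1_documented_negative_antibodies
#' @return a `"branch_result"`.
#' @export
branch_5_t1d_ruled_out <- function(x, ids) {
  fl <- x$ml_flags
  ruled <- stats::setNames(fl$ml_t1d_ruled_out, fl$patient_id)
  eval_branch(5L, ids, function(id) isTRUE(ruled[[id]]))
}

#' Branch 6: not called T1D by the high-PPV phenotype flag
#'
#' Keeps patients whose `ml_t1d_high_ppv` flag (PPV 0.95 against chart
#' review) is `FALSE` or absent.
#'
#' @inheritParams branch_1_documented_negative_antibodies
#' @return a `"branch_result"`.
#' @export
branch_6_not_confident_t1d <- function(x, ids) {
  fl <- x$ml_flags
  high <- stats::setNames(fl$ml_t1d_high_ppv, fl$patient_id)
  eval_branch(6L, ids, function(id) !isTRUE(high[[id]]))
}

med_split <- function(x, cutoff_date = NULL) {
  m <- x$medications
  if (!is.null(cutoff_date)) m <- m[m$date <= cutoff_date, , drop = FALSE]
  split(m, m$patient_id)
}

#' Run all six branch algorithms
#'
#' @param x an `"adscreen_cohort"`.
#' @param ids the base-algorithm kept set.
#' @param require_full_panel passed to branch 1.
#' @param cutoff_date passed to the medication branches (2--4).
#' @return list of six `"branch_result"` objects, in branch order.
#' @export
run_branches <- function(x, ids, require_full_panel = FALSE,
                         cutoff_date = NULL) {
  list(branch_1_documented_negative_antibodies(x, ids, require_full_panel),
       branch_2_no_outpatient_insulin(x, ids, cutoff_date),
       branch_3_t2d_specific_med(x, ids, cutoff_date),
       branch_4_t2d_med_or_metformin(x, ids, cutoff_date),
       branch_5_t1d_ruled_out(x, ids),
       branch_6_not_confident_t1d(x, ids))
}

#' Assemble the candidate union from six branch results
#'
#' @param branch_results list of six `"branch_result"` objects over the
#'   same input set.
#' @return list of class `"candidate_set"`: `union_ids` (sorted) and
#'   `membership`, a logical matrix (union members x 6 branches) whose
#'   rows each contain at least one `TRUE`.
#' @export
assemble_candidates <- function(branch_results) {
  stopifnot(length(branch_results) == 6)
  inputs <- lapply(branch_results, function(b) sort(c(b$kept, b$excluded)))
  for (i in 2:6) {
    if (!identical(inputs[[i]], inputs[[1]])) {
      stop("branch results cover different input sets (branch ", i, ")")
    }
  }
  union_ids <- sort(unique(unlist(lapply(branch_results, `[[`, "kept"))))
  membership <- vapply(branch_results,
                       function(b) union_ids %in% b$kept,
                       logical(length(union_ids)))
  membership <- matrix(membership, nrow = length(union_ids), ncol = 6,
                       dimnames = list(union_ids, paste0("branch_", 1:6)))
  structure(list(union_ids = union_ids, membership = membership),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> %d candidates; per-branch kept: %s\n",
              length(x$union_ids),
              paste(colSums(x$membership), collapse = "/")))
  invisible(x)
}
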