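# Base exclusion algorithm: starting from the ML-flagged T2D group, remove
# patients with evidence of typical (metabolic) T2D, cystic fibrosis-related
# diabetes, or laboratory-demonstrated autoimmune diabetes, and patients
# with too little BMI data to trust the phenotype.

#' Base-algorithm configuration
#'
#' Thresholds of the typical-T2D exclusion filter. All lab/BMI comparisons
#' are strict ("ever less than" / "ever greater than"), so boundary values
#' survive. The criteria need not be met concurrently: a single value ever
#' outside a threshold excludes the patient.
#'
#' @param hdl_floor mg/dL; patients with any HDL strictly below this are
#'   excluded (metabolic syndrome evidence). Default 50.
#' @param tg_ceiling mg/dL; any triglyceride value strictly above excludes.
#'   Default 150.
#' @param bmi_ceiling kg/m^2; any BMI strictly above excludes. Default 30.
#' @param min_bmi_count minimum number of normal-range BMI records required
#'   to count as reliably engaged with the healthcare system. Default 3.
#' @param bmi_normal_ceiling kg/m^2; a BMI record counts toward
#'   `min_bmi_count` when `value <= bmi_normal_ceiling`. Default 30: the
#'   obesity-range exclusion already removes records above 30, and the
#'   criterion's purpose is engagement, not normality. Set to 24.9 (with
#'   `bmi_normal_floor = 18.5`) for a strict normal-weight reading.
#' @param bmi_normal_floor kg/m^2 lower bound for a qualifying BMI record.
#'   Default 0 (no lower bound).
#' @param cf_code_set character vector of diagnosis-code prefixes that mark
#'   cystic fibrosis (defaults: ICD-9 277.0, ICD-10 E84; prefix match).
#' @param antibody_panel islet autoantibodies whose positivity excludes.
#' @return list of class `"base_filter_config"`.
#' @export
base_filter_config <- function(hdl_floor = 50, tg_ceiling = 150,
                               bmi_ceiling = 30, min_bmi_count = 3,
                               bmi_normal_ceiling = 30,
                               bmi_normal_floor = 0,
                               cf_code_set = c("277.0", "E84"),
                               antibody_panel = ANTIBODY_PANEL) {
  stopifnot(hdl_floor > 0, tg_ceiling > 0, bmi_ceiling > 0,
            min_bmi_count >= 1, bmi_normal_ceiling > 0)
  structure(list(hdl_floor = hdl_floor, tg_ceiling = tg_ceiling,
                 bmi_ceiling = bmi_ceiling, min_bmi_count = min_bmi_count,
                 bmi_normal_ceiling = bmi_normal_ceiling,
                 bmi_normal_floor = bmi_normal_floor,
                 cf_code_set = cf_code_set,
                 antibody_panel = antibody_panel),
            class = "base_filter_config")
}

#' Did an analyte ever cross a threshold?
#'
#' @param labs data.frame of lab results (`analyte`, `value`, `date`).
#' @param analyte one of `"HDL"`, `"TG"`, `"HbA1c"`.
#' @param threshold numeric threshold.
#' @param direction `"below"` (ever strictly less than the threshold) or
#'   `"above"` (ever strictly greater). Strict inequality throughout, so a
#'   value exactly at the threshold does not trigger.
#' @return `TRUE`/`FALSE`; an empty or absent analyte yields `FALSE`
#'   (absence of evidence does not exclude).
#' @export
ever_outside <- function(labs, analyte, threshold,
                         direction = c("below", "above")) {
  direction <- match.arg(direction)
  v <- labs$value[labs$analyte == analyte]
  v <- v[!is.na(v)]
  if (length(v) == 0) return(FALSE)
  if (direction == "below") any(v < threshold) else any(v > threshold)
}

#' Sufficient healthcare engagement via BMI record count
#'
#' `TRUE` when the patient has at least `min_bmi_count` BMI records in the
#' configured normal range (`bmi_normal_floor` <= value <=
#' `bmi_normal_ceiling`).
#'
#' @param bmi data.frame of BMI measurements (`value`, `date`).
#' @param config a [base_filter_config()].
#' @export
has_engagement <- function(bmi, config = base_filter_config()) {
  v <- bmi$value[!is.na(bmi$value)]
  sum(v >= config$bmi_normal_floor & v <= config$bmi_normal_ceiling) >=
    config$min_bmi_count
}

#' Any cystic fibrosis diagnosis code?
#'
#' Prefix match against the configured CF code set (ICD-9 277.0x and
#' ICD-10 E84.* by default).
#'
#' @param diagnoses data.frame of diagnosis codes (`code`, `date`).
#' @param cf_code_set character vector of code prefixes.
#' @export
has_cf <- function(diagnoses, cf_code_set = c("277.0", "E84")) {
  codes <- diagnoses$code[!is.na(diagnoses$code)]
  if (length(codes) == 0) return(FALSE)
  any(vapply(cf_code_set, function(p) any(startsWith(codes, p)),
             logical(1)))
}

#' Any positive islet autoantibody?
#'
#' `TRUE` iff any test of an antibody in the panel was ever positive.
#' Untested patients (no rows) are not positive.
#'
#' @param antibodies data.frame of antibody tests (`antibody`, `result`,
#'   `date`).
#' @param panel antibodies considered, default GAD65/IA2/ZnT8.
#' @export
has_positive_antibody <- function(antibodies, panel = ANTIBODY_PANEL) {
  any(antibodies$antibody %in% panel & antibodies$result == "positive")
}

BASE_CRITERIA <- c("metabolic_hdl", "metabolic_tg", "metabolic_bmi",
                   "engagement", "cf", "antibody")

#' Apply the base exclusion algorithm
#'
#' Input is the ML-flagged T2D group of the cohort (`ml_t2d == TRUE`).
#' Each exclusion criterion is evaluated as an independent predicate on the
#' patient's full longitudinal record, and a patient may be tagged under
#' several criteria; the kept set is the patients excluded by none. The
#' fixed criterion order is: `metabolic_hdl`, `metabolic_tg`,
#' `metabolic_bmi`, `engagement` (fewer than `min_bmi_count` qualifying BMI
#' records), `cf`, `antibody`.
#'
#' @param x an `"adscreen_cohort"`.
#' @param config a [base_filter_config()].
#' @return list of class `"filter_result"`: `kept` (patient ids, sorted),
#'   `excluded` (named list criterion -> ids), `input_size`, and
#'   `attrition` (data.frame criterion / n_excluded / n_remaining under
#'   sequential application in the fixed order).
#' @export
apply_base_algorithm <- function(x, config = base_filter_config()) {
  validate_cohort(x)
  input <- sort(x$ml_flags$patient_id[!is.na(x$ml_flags$ml_t2d) &
                                        x$ml_flags$ml_t2d])
  labs <- split(x$labs, x$labs$patient_id)
  bmis <- split(x$bmi, x$bmi$patient_id)
  dxs <- split(x$diagnoses, x$diagnoses$patient_id)
  abs_ <- split(x$antibodies, x$antibodies$patient_id)
  empty <- empty_entity_tables()
  get <- function(lst, id, name) lst[[id]] %||% empty[[name]]

  flag <- function(id) {
    L <- get(labs, id, "labs")
    B <- get(bmis, id, "bmi")
    c(metabolic_hdl = ever_outside(L, "HDL", config$hdl_floor, "below"),
      metabolic_tg = ever_outside(L, "TG", config$tg_ceiling, "above"),
      metabolic_bmi = {
        v <- B$value[!is.na(B$value)]
        length(v) > 0 && any(v > config$bmi_ceiling)
      },
      engagement = !has_engagement(B, config),
      cf = has_cf(get(dxs, id, "diagnoses"), config$cf_code_set),
      antibody = has_positive_antibody(get(abs_, id, "antibodies"),
                                       config$antibody_panel))
  }
  hits <- if (length(input) == 0) {
    matrix(logical(0), nrow = 0, ncol = length(BASE_CRITERIA),
           dimnames = list(NULL, BASE_CRITERIA))
  } else {
    t(vapply(input, flag, logical(length(BASE_CRITERIA))))
  }
  excluded <- lapply(stats::setNames(BASE_CRITERIA, BASE_CRITERIA),
                     function(cr) input[hits[, cr]])
  kept <- input[rowSums(hits) == 0]
  # sequential attrition view: criterion k counts exclusions among patients
  # not already removed by criteria 1..k-1
  remaining <- rep(TRUE, length(input))
  attr_rows <- lapply(BASE_CRITERIA, function(cr) {
    newly <- remaining & hits[, cr]
    remaining <<- remaining & !hits[, cr]
    data.frame(criterion = cr, n_excluded = sum(newly),
               n_remaining = sum(remaining), stringsAsFactors = FALSE)
  })
  structure(list(kept = kept, excluded = excluded,
                 input_size = length(input),
                 attrition = do.call(rbind, attr_rows)),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("<filter_result> input %d -> kept %d\n", x$input_size,
              length(x$kept)))
  print(x$attrition, row.names = FALSE)
  invisible(x)
}
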