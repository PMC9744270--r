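# Entity-table cohort container and interchange readers/writers.
#
# A cohort is stored relationally, mirroring a typical EHR research extract:
# one data.frame per entity type (patients, labs, bmi, medications,
# diagnoses, antibodies, ml_flags, chart_facts), joined on patient_id.

LAB_ANALYTES <- c("HDL", "TG", "HbA1c")

SEX_LEVELS <- c("F", "M", "unknown")

RACE_LEVELS <- c("White", "Black", "Hispanic", "Asian", "Other", "Unknown")

DRUG_CLASSES <- c("insulin", "metformin", "sulfonylurea", "meglitinide",
                  "TZD", "DPP4i", "AGI", "GLP1RA", "SGLT2i",
                  "systemic_steroid", "other")

#' Diabetes drug classes counted as "T2D-specific"
#'
#' Sulfonylureas, meglitinides, thiazolidinediones, DPP-4 inhibitors,
#' alpha-glucosidase inhibitors, GLP-1 receptor agonists and SGLT2
#' inhibitors. Metformin and insulin are deliberately not in this set:
#' metformin is used across diabetes types (and beyond), and insulin is the
#' hallmark the branch filters treat separately.
#' @export
T2D_SPECIFIC_CLASSES <- c("sulfonylurea", "meglitinide", "TZD", "DPP4i",
                          "AGI", "GLP1RA", "SGLT2i")

# Diabetes drug classes other than insulin (used when counting non-insulin
# diabetes agents in a regimen; systemic steroids are not diabetes drugs).
NONINSULIN_DM_CLASSES <- c("metformin", T2D_SPECIFIC_CLASSES)

C_PEPTIDE_LEVELS <- c("low", "normal_or_high", "untested")
MODY_TEST_LEVELS <- c("positive", "negative", "untested")
ANTIBODY_PANEL <- c("GAD65", "IA2", "ZnT8")

CHART_FACT_FIELDS <- c("age_at_diagnosis", "age_at_diagnosis_is_upper_bound",
                       "ketosis_history_adult", "c_peptide_status",
                       "mody_genetic_test", "family_history_diabetes",
                       "multigenerational_family_history",
                       "pancreatic_disease_before_dx",
                       "chronic_steroid_exposure_at_dx",
                       "insulin_dependent_from_onset",
                       "long_term_insulin_use", "bmi_at_diagnosis")

ENTITY_TABLES <- c("patients", "labs", "bmi", "medications", "diagnoses",
                   "antibodies", "ml_flags", "chart_facts")

empty_entity_tables <- function() {
  list(
    patients = data.frame(patient_id = character(), sex = character(),
                          birth_year = integer(),
                          race_ethnicity = character(),
                          stringsAsFactors = FALSE),
    labs = data.frame(patient_id = character(), analyte = character(),
                      value = numeric(), date = as.Date(character()),
                      stringsAsFactors = FALSE),
    bmi = data.frame(patient_id = character(), value = numeric(),
                     date = as.Date(character()), stringsAsFactors = FALSE),
    medications = data.frame(patient_id = character(),
                             drug_name = character(),
                             drug_class = character(), setting = character(),
                             date = as.Date(character()),
                             stringsAsFactors = FALSE),
    diagnoses = data.frame(patient_id = character(), code = character(),
                           date = as.Date(character()),
                           stringsAsFactors = FALSE),
    antibodies = data.frame(patient_id = character(), antibody = character(),
                            result = character(), date = as.Date(character()),
                            stringsAsFactors = FALSE),
    ml_flags = data.frame(patient_id = character(), ml_t2d = logical(),
                          ml_t1d_high_ppv = logical(),
                          ml_t1d_ruled_out = logical(),
                          stringsAsFactors = FALSE),
    chart_facts = data.frame(patient_id = character(),
                             age_at_diagnosis = numeric(),
                             age_at_diagnosis_is_upper_bound = logical(),
                             ketosis_history_adult = logical(),
                             c_peptide_status = character(),
                             mody_genetic_test = character(),
                             family_history_diabetes = logical(),
                             multigenerational_family_history = logical(),
                             pancreatic_disease_before_dx = logical(),
                             chronic_steroid_exposure_at_dx = logical(),
                             insulin_dependent_from_onset = logical(),
                             long_term_insulin_use = logical(),
                             bmi_at_diagnosis = numeric(),
                             stringsAsFactors = FALSE)
  )
}

#' Construct an EHR cohort
#'
#' Bundles the eight entity tables of the relational cohort layout into a
#' single validated object of class `"adscreen_cohort"`. Missing tables
#' default to empty; every child table must reference a patient present in
#' `patients`.
#'
#' @param patients data.frame with columns `patient_id`, `sex`,
#'   `birth_year`, `race_ethnicity`.
#' @param labs data.frame of laboratory results (`patient_id`, `analyte`
#'   in `HDL`/`TG`/`HbA1c`, `value`, `date`). HDL and triglycerides are in
#'   mg/dL, HbA1c in percent.
#' @param bmi data.frame of BMI measurements (`patient_id`, `value` in
#'   kg/m^2, `date`).
#' @param medications data.frame of medication exposures (`patient_id`,
#'   `drug_name`, `drug_class`, `setting` in `outpatient`/`inpatient`,
#'   `date`). `drug_class` may be `NA`, in which case it is resolved from
#'   `drug_name` via [med_vocabulary()].
#' @param diagnoses data.frame of diagnosis codes (`patient_id`, `code`,
#'   `date`).
#' @param antibodies data.frame of islet autoantibody tests (`patient_id`,
#'   `antibody` in `GAD65`/`IA2`/`ZnT8`, `result` in
#'   `positive`/`negative`, `date`).
#' @param ml_flags data.frame of curated-phenotype flags (`patient_id`,
#'   `ml_t2d`, `ml_t1d_high_ppv`, `ml_t1d_ruled_out`). Patients absent
#'   from this table are treated as unflagged.
#' @param chart_facts data.frame of chart-review facts, one row per
#'   reviewed patient; `NA` means "not documented", which downstream
#'   classification treats differently from a documented `FALSE`.
#' @param provenance free-text label describing where the cohort came from.
#' @param seed integer seed the cohort was generated from, or `NA`.
#' @return An object of class `"adscreen_cohort"`: a list of the eight
#'   entity data.frames plus `provenance` and `seed`.
#' @seealso [read_cohort()], [write_cohort()], [generate_cohort()]
#' @export
cohort <- function(patients, labs = NULL, bmi = NULL, medications = NULL,
                   diagnoses = NULL, antibodies = NULL, ml_flags = NULL,
                   chart_facts = NULL, provenance = "unspecified",
                   seed = NA_integer_) {
  tmpl <- empty_entity_tables()
  fill <- function(x, name) {
    if (is.null(x) || nrow(x) == 0) return(tmpl[[name]])
    missing_cols <- setdiff(names(tmpl[[name]]), names(x))
    if (length(missing_cols) > 0) {
      stop(sprintf("table '%s' is missing column(s): %s", name,
                   paste(missing_cols, collapse = ", ")))
    }
    x <- as.data.frame(x)[names(tmpl[[name]])]
    rownames(x) <- NULL
    x
  }
  obj <- structure(
    list(patients = fill(patients, "patients"),
         labs = fill(labs, "labs"),
         bmi = fill(bmi, "bmi"),
         medications = fill(medications, "medications"),
         diagnoses = fill(diagnoses, "diagnoses"),
         antibodies = fill(antibodies, "antibodies"),
         ml_flags = fill(ml_flags, "ml_flags"),
         chart_facts = fill(chart_facts, "chart_facts"),
         provenance = provenance,
         seed = seed),
    class = "adscreen_cohort")
  if (nrow(obj$medications) > 0) {
    cls <- obj$medications$drug_class
    need <- is.na(cls) | cls == ""
    if (any(need)) {
      cls[need] <- resolve_drug_class(obj$medications$drug_name[need])
    }
    obj$medications$drug_class <- cls
  }
  validate_cohort(obj)
  obj
}

#' Validate a cohort object
#'
#' Checks patient-id uniqueness, referential integrity of every child
#' table, enum domains, physiologic value ranges (HbA1c in 3--20%, BMI in
#' 10--100 kg/m^2, positive lab values) and the phenotype-flag invariant
#' that a patient cannot simultaneously carry the high-PPV T1D call and the
#' T1D rule-out.
#'
#' @param x an `"adscreen_cohort"`.
#' @return `x`, invisibly; stops with a message on the first violation.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "adscreen_cohort"))
  ids <- x$patients$patient_id
  if (anyDuplicated(ids)) {
    stop("duplicate patient_id in patients table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (!is.character(x$provenance) || length(x$provenance) != 1 ||
      !nzchar(x$provenance)) {
    stop("provenance must be a nonempty string")
  }
  check_enum <- function(vals, levels, what) {
    bad <- setdiff(unique(vals[!is.na(vals)]), levels)
    if (length(bad) > 0) {
      stop(sprintf("invalid %s value(s): %s", what,
                   paste(bad, collapse = ", ")))
    }
  }
  check_enum(x$patients$sex, SEX_LEVELS, "sex")
  check_enum(x$patients$race_ethnicity, RACE_LEVELS, "race_ethnicity")
  check_enum(x$labs$analyte, LAB_ANALYTES, "lab analyte")
  check_enum(x$medications$drug_class, DRUG_CLASSES, "drug_class")
  check_enum(x$medications$setting, c("outpatient", "inpatient"), "setting")
  check_enum(x$antibodies$antibody, ANTIBODY_PANEL, "antibody")
  check_enum(x$antibodies$result, c("positive", "negative"),
             "antibody result")
  check_enum(x$chart_facts$c_peptide_status, C_PEPTIDE_LEVELS,
             "c_peptide_status")
  check_enum(x$chart_facts$mody_genetic_test, MODY_TEST_LEVELS,
             "mody_genetic_test")
  for (tab in setdiff(ENTITY_TABLES, "patients")) {
    orphan <- setdiff(x[[tab]]$patient_id, ids)
    if (length(orphan) > 0) {
      stop(sprintf("table '%s' references unknown patient id(s): %s", tab,
                   paste(utils::head(orphan, 5), collapse = ", ")))
    }
  }
  if (nrow(x$ml_flags) > 0 && anyDuplicated(x$ml_flags$patient_id)) {
    stop("duplicate patient_id in ml_flags table")
  }
  if (nrow(x$chart_facts) > 0 && anyDuplicated(x$chart_facts$patient_id)) {
    stop("duplicate patient_id in chart_facts table")
  }
  with(x$ml_flags, if (any(!is.na(ml_t1d_high_ppv) &
                           !is.na(ml_t1d_ruled_out) &
                           ml_t1d_high_ppv & ml_t1d_ruled_out)) {
    stop("ml_t1d_high_ppv and ml_t1d_ruled_out are mutually exclusive")
  })
  if (nrow(x$labs) > 0) {
    if (any(!is.na(x$labs$value) & x$labs$value <= 0)) {
      stop("lab values must be positive")
    }
    a1c <- x$labs$value[x$labs$analyte == "HbA1c"]
    if (any(!is.na(a1c) & (a1c < 3 | a1c > 20))) {
      stop("HbA1c values must lie in [3, 20] percent")
    }
  }
  if (nrow(x$bmi) > 0 &&
      any(!is.na(x$bmi$value) & (x$bmi$value < 10 | x$bmi$value > 100))) {
    stop("BMI values must lie in [10, 100] kg/m^2")
  }
  dated <- c("labs", "bmi", "medications", "diagnoses", "antibodies")
  for (tab in dated) {
    if (nrow(x[[tab]]) > 0 && any(is.na(x[[tab]]$date))) {
      stop(sprintf("table '%s' contains missing dates", tab))
    }
  }
  invisible(x)
}

#' @export
print.adscreen_cohort <- function(x, ...) {
  cat(sprintf("<adscreen_cohort> %d patients (%s)\n",
              nrow(x$patients), x$provenance))
  for (tab in setdiff(ENTITY_TABLES, "patients")) {
    cat(sprintf("  %-12s %6d rows\n", tab, nrow(x[[tab]])))
  }
  invisible(x)
}

#' Number of patients in a cohort
#' @param x an `"adscreen_cohort"`.
#' @export
n_patients <- function(x) nrow(x$patients)

#' Extract one patient's longitudinal record
#'
#' @param x an `"adscreen_cohort"`.
#' @param id patient identifier.
#' @return A list with the patient's demographics row and slices of every
#'   child table, in the entity layout (`labs`, `bmi`, `medications`,
#'   `diagnoses`, `antibodies`, `ml_flags`, `chart_facts`).
#' @export
patient_record <- function(x, id) {
  stopifnot(inherits(x, "adscreen_cohort"), length(id) == 1)
  if (!id %in% x$patients$patient_id) stop("unknown patient id: ", id)
  slice <- function(tab) {
    out <- tab[tab$patient_id == id, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(patient = slice(x$patients),
       labs = slice(x$labs),
       bmi = slice(x$bmi),
       medications = slice(x$medications),
       diagnoses = slice(x$diagnoses),
       antibodies = slice(x$antibodies),
       ml_flags = slice(x$ml_flags),
       chart_facts = slice(x$chart_facts))
}

# --- dates -----------------------------------------------------------------

#' Parse EHR dates, accepting year-only entries
#'
#' Full ISO-8601 dates (`YYYY-MM-DD`) are parsed at day resolution.
#' Year-only entries (`YYYY`) — common for historical diagnosis dates — are
#' mapped to July 1 of that year: only the ordering of dates is consumed by
#' the filtering algorithms, so mid-year placement minimises ordering bias
#' in either direction.
#'
#' @param x character vector of dates.
#' @return a `Date` vector; unparseable entries raise an error.
#' @export
parse_ehr_date <- function(x) {
  x <- as.character(x)
  out <- rep(as.Date(NA), length(x))
  blank <- is.na(x) | x == ""
  year_only <- !blank & grepl("^[0-9]{4}$", x)
  if (any(year_only)) {
    out[year_only] <- as.Date(paste0(x[year_only], "-07-01"))
  }
  full <- !blank & !year_only
  parsed <- rep(as.Date(NA), length(x))
  parsed[full] <- as.Date(x[full], format = "%Y-%m-%d")
  bad <- full & is.na(parsed)
  if (any(bad)) {
    stop("unparseable date(s): ", paste(utils::head(x[bad], 5),
                                        collapse = ", "))
  }
  out[full] <- parsed[full]
  out
}

# --- most recent measurement -----------------------------------------------

#' Most recent measurement in a dated list
#'
#' Returns the entry with the maximum date. Same-day ties are broken by
#' taking the largest value, so reports are reproducible regardless of the
#' storage order of the input rows.
#'
#' @param x data.frame with (at least) columns `value` and `date`.
#' @return the selected single row, or `NULL` for an empty input.
#' @export
most_recent <- function(x) {
  if (is.null(x) || nrow(x) == 0) return(NULL)
  ord <- order(x$date, x$value)
  out <- x[ord[length(ord)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- medication vocabulary -------------------------------------------------

#' Default medication vocabulary
#'
#' Maps lower-case generic (and a few brand) drug names to the drug classes
#' the filtering algorithms reason over. Users can extend or replace the
#' table; [resolve_drug_class()] falls back to class `other` (with a
#' warning) for names it does not know.
#'
#' @return named character vector: `names()` are drug names, values are
#'   classes from `DRUG_CLASSES`.
#' @export
med_vocabulary <- function() {
  c(
    # insulins
    "insulin" = "insulin", "basal insulin" = "insulin",
    "insulin glargine" = "insulin", "insulin detemir" = "insulin",
    "insulin degludec" = "insulin", "insulin lispro" = "insulin",
    "insulin aspart" = "insulin", "insulin nph" = "insulin",
    "insulin regular" = "insulin", "lantus" = "insulin",
    "humalog" = "insulin", "novolog" = "insulin",
    # biguanide
    "metformin" = "metformin", "glucophage" = "metformin",
    # sulfonylureas
    "glipizide" = "sulfonylurea", "glyburide" = "sulfonylurea",
    "glimepiride" = "sulfonylurea", "chlorpropamide" = "sulfonylurea",
    "tolbutamide" = "sulfonylurea",
    # meglitinides
    "repaglinide" = "meglitinide", "nateglinide" = "meglitinide",
    # thiazolidinediones
    "pioglitazone" = "TZD", "rosiglitazone" = "TZD",
    # DPP-4 inhibitors
    "sitagliptin" = "DPP4i", "saxagliptin" = "DPP4i",
    "linagliptin" = "DPP4i", "alogliptin" = "DPP4i",
    # alpha-glucosidase inhibitors
    "acarbose" = "AGI", "miglitol" = "AGI",
    # GLP-1 receptor agonists
    "liraglutide" = "GLP1RA", "semaglutide" = "GLP1RA",
    "exenatide" = "GLP1RA", "dulaglutide" = "GLP1RA",
    "lixisenatide" = "GLP1RA",
    # SGLT2 inhibitors
    "empagliflozin" = "SGLT2i", "canagliflozin" = "SGLT2i",
    "dapagliflozin" = "SGLT2i", "ertugliflozin" = "SGLT2i",
    # systemic steroids
    "prednisone" = "systemic_steroid", "prednisolone" = "systemic_steroid",
    "dexamethasone" = "systemic_steroid",
    "methylprednisolone" = "systemic_steroid",
    "hydrocortisone" = "systemic_steroid"
  )
}

#' Resolve drug names to drug classes
#'
#' @param drug_name character vector of drug names.
#' @param vocabulary named class vector, defaults to [med_vocabulary()].
#' @return character vector of drug classes; unknown names map to
#'   `"other"` with a single warning listing them.
#' @export
resolve_drug_class <- function(drug_name, vocabulary = med_vocabulary()) {
  key <- tolower(trimws(drug_name))
  # tolerate parenthetical annotations, e.g. "metformin (discontinued)"
  key <- trimws(sub("\\s*\\(.*\\)$", "", key))
  cls <- unname(vocabulary[key])
  unknown <- is.na(cls) & !is.na(key) & nzchar(key)
  if (any(unknown)) {
    warning("unknown drug name(s) mapped to class 'other': ",
            paste(unique(key[unknown]), collapse = ", "))
    cls[unknown] <- "other"
  }
  cls
}

# --- interchange: directory of CSV entity tables ---------------------------

#' Read a cohort from an entity-table bundle
#'
#' The bundle is either a directory holding one UTF-8 comma-delimited file
#' per entity type (`patients.csv` mandatory, the rest optional) with
#' ISO-8601 (or year-only) dates, or a JSON-lines file (`*.jsonl`) with one
#' patient object per line carrying the same fields nested under the entity
#' names.
#'
#' @param path bundle directory or `.jsonl` file.
#' @return an `"adscreen_cohort"`.
#' @export
read_cohort <- function(path) {
  if (file.exists(path) && !dir.exists(path) && grepl("\\.jsonl$", path)) {
    return(read_cohort_jsonl(path))
  }
  if (!dir.exists(path)) stop("bundle directory not found: ", path)
  pfile <- file.path(path, "patients.csv")
  if (!file.exists(pfile)) stop("bundle has no patients table: ", pfile)
  read_tab <- function(name) {
    f <- file.path(path, paste0(name, ".csv"))
    if (!file.exists(f)) return(NULL)
    utils::read.csv(f, stringsAsFactors = FALSE,
                    colClasses = "character")
  }
  tabs <- lapply(stats::setNames(ENTITY_TABLES, ENTITY_TABLES), read_tab)
  tmpl <- empty_entity_tables()
  coerce <- function(df, name) {
    if (is.null(df)) return(NULL)
    proto <- tmpl[[name]]
    for (col in names(proto)) {
      if (!col %in% names(df)) {
        stop(sprintf("table '%s' is missing column '%s'", name, col))
      }
      target <- class(proto[[col]])[1]
      df[[col]] <- switch(target,
        "character" = as.character(df[[col]]),
        "numeric" = parse_numeric(df[[col]], name, col),
        "integer" = as.integer(parse_numeric(df[[col]], name, col)),
        "logical" = parse_logical(df[[col]], name, col),
        "Date" = parse_ehr_date(df[[col]]),
        df[[col]])
    }
    df[names(proto)]
  }
  meta <- read_bundle_meta(path)
  cohort(patients = coerce(tabs$patients, "patients"),
         labs = coerce(tabs$labs, "labs"),
         bmi = coerce(tabs$bmi, "bmi"),
         medications = coerce(tabs$medications, "medications"),
         diagnoses = coerce(tabs$diagnoses, "diagnoses"),
         antibodies = coerce(tabs$antibodies, "antibodies"),
         ml_flags = coerce(tabs$ml_flags, "ml_flags"),
         chart_facts = coerce(tabs$chart_facts, "chart_facts"),
         provenance = meta$provenance, seed = meta$seed)
}

parse_numeric <- function(x, tab, col) {
  x[x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop(sprintf("unparseable numeric value(s) in %s$%s: %s", tab, col,
                 paste(utils::head(x[bad], 5), collapse = ", ")))
  }
  out
}

parse_logical <- function(x, tab, col) {
  x[x == ""] <- NA_character_
  out <- rep(NA, length(x))
  out[!is.na(x) & toupper(x) %in% c("TRUE", "T", "1")] <- TRUE
  out[!is.na(x) & toupper(x) %in% c("FALSE", "F", "0")] <- FALSE
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop(sprintf("unparseable logical value(s) in %s$%s: %s", tab, col,
                 paste(utils::head(x[bad], 5), collapse = ", ")))
  }
  out
}

read_bundle_meta <- function(path) {
  f <- file.path(path, "cohort_meta.json")
  if (!file.exists(f)) {
    return(list(provenance = paste0("bundle:", basename(path)),
                seed = NA_integer_))
  }
  meta <- jsonlite::read_json(f, simplifyVector = TRUE)
  list(provenance = meta$provenance %||% paste0("bundle:", basename(path)),
       seed = if (is.null(meta$seed) || is.na(meta$seed)) NA_integer_
              else as.integer(meta$seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cohort as an entity-table bundle
#'
#' Writes all eight entity tables (header-only when empty) plus a
#' `cohort_meta.json` carrying provenance and seed. Rows are ordered
#' deterministically (patient_id, then date, then remaining columns), so
#' two writes of the same cohort are byte-identical and
#' `read_cohort(write_cohort(x))` is the identity.
#'
#' @param x an `"adscreen_cohort"`.
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  validate_cohort(x)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create bundle directory: ", path)
  for (tab in ENTITY_TABLES) {
    df <- x[[tab]]
    if (nrow(df) > 0) {
      ord <- do.call(order, unname(as.list(df)))
      df <- df[ord, , drop = FALSE]
    }
    for (col in names(df)) {
      if (inherits(df[[col]], "Date")) df[[col]] <- format(df[[col]])
    }
    utils::write.csv(df, file.path(path, paste0(tab, ".csv")),
                     row.names = FALSE, quote = TRUE, na = "")
  }
  jsonlite::write_json(
    list(provenance = x$provenance,
         seed = if (is.na(x$seed)) NULL else x$seed),
    file.path(path, "cohort_meta.json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

# JSON-lines dialect: one patient object per line, child entities nested.
read_cohort_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  tmpl <- empty_entity_tables()
  pull <- function(name, fields) {
    rows <- lapply(recs, function(r) {
      part <- r[[name]]
      if (is.null(part) || NROW(part) == 0) return(NULL)
      part <- as.data.frame(part, stringsAsFactors = FALSE)
      part$patient_id <- r$patient_id
      part
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0) return(NULL)
    out <- do.call(rbind, rows)
    if ("date" %in% names(out)) out$date <- parse_ehr_date(out$date)
    out
  }
  patients <- do.call(rbind, lapply(recs, function(r) {
    data.frame(patient_id = r$patient_id,
               sex = r$sex %||% "unknown",
               birth_year = as.integer(r$birth_year),
               race_ethnicity = r$race_ethnicity %||% "Unknown",
               stringsAsFactors = FALSE)
  }))
  flags <- do.call(rbind, lapply(recs, function(r) {
    f <- r$ml_flags
    if (is.null(f)) return(NULL)
    data.frame(patient_id = r$patient_id,
               ml_t2d = isTRUE(f$ml_t2d),
               ml_t1d_high_ppv = isTRUE(f$ml_t1d_high_ppv),
               ml_t1d_ruled_out = isTRUE(f$ml_t1d_ruled_out),
               stringsAsFactors = FALSE)
  }))
  charts <- do.call(rbind, lapply(recs, function(r) {
    cf <- r$chart
    if (is.null(cf)) return(NULL)
    row <- tmpl$chart_facts[0, ]
    row[1, "patient_id"] <- r$patient_id
    for (fld in CHART_FACT_FIELDS) {
      if (!is.null(cf[[fld]])) row[1, fld] <- cf[[fld]]
    }
    row
  }))
  cohort(patients = patients, labs = pull("labs"), bmi = pull("bmi"),
         medications = pull("medications"), diagnoses = pull("diagnoses"),
         antibodies = pull("antibodies"), ml_flags = flags,
         chart_facts = charts,
         provenance = paste0("jsonl:", basename(path)))
}
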