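#' Encounter cohorts
#'
#' A cohort is a data.frame with one row per surgical encounter and columns:
#' `encounter_id` (unique), `patient_id`, `age` (integer years, may be NA),
#' `date` (Date, may be NA), `dx_codes` and `proc_codes` (`";"`-separated
#' canonical codes, `""` for none) and `reference_label` (`"case"`,
#' `"control"` or `"unknown"` when no chart-review reference exists).
#'
#' @name encounter-cohort
NULL

COHORT_COLUMNS <- c("encounter_id", "patient_id", "age", "date",
                    "dx_codes", "proc_codes", "reference_label")

#' Validate an encounter cohort
#'
#' Checks the column contract above and uniqueness of encounter ids.
#'
#' @param cohort a data.frame.
#' @return the cohort, invisibly, with canonical column order.
#' @export
validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) abort_input("cohort must be a data.frame")
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols)) {
    abort_input(paste("cohort is missing columns:",
                      paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(cohort$encounter_id)) {
    abort_input("duplicate encounter_id values in cohort")
  }
  bad <- !cohort$reference_label %in% c("case", "control", "unknown")
  if (any(bad)) {
    abort_input("reference_label must be case, control or unknown")
  }
  invisible(cohort[, COHORT_COLUMNS])
}

empty_cohort <- function() {
  data.frame(
    encounter_id = character(0), patient_id = character(0),
    age = integer(0), date = as.Date(character(0)),
    dx_codes = character(0), proc_codes = character(0),
    reference_label = character(0), stringsAsFactors = FALSE
  )
}

#' Read / write encounter cohorts as CSV
#'
#' The CSV dialect has a header row with the columns documented in
#' \link{encounter-cohort}; `dx_codes`/`proc_codes` hold `";"`-separated raw
#' codes, `date` is ISO-8601, `reference_label` may be empty (read as
#' `"unknown"`). Codes are normalized on read.
#'
#' @param path file path.
#' @return `read_encounters()` returns a validated cohort data.frame.
#' @export
read_encounters <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("no such file: %s", path))
  raw <- utils::read.csv(path, colClasses = "character")
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols)) {
    abort_input(paste0(path, ": missing columns: ",
                       paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0L) return(empty_cohort())
  norm_field <- function(x, system) {
    codes <- split_codes(x)
    join_codes(lapply(codes, function(v) {
      if (length(v) == 0L) character(0) else normalize_code(v, system)
    }))
  }
  out <- data.frame(
    encounter_id = raw$encounter_id,
    patient_id = raw$patient_id,
    age = suppressWarnings(as.integer(raw$age)),
    date = as.Date(ifelse(nzchar(raw$date), raw$date, NA_character_)),
    dx_codes = norm_field(raw$dx_codes, "ICD10"),
    proc_codes = norm_field(raw$proc_codes, "CCI"),
    reference_label = ifelse(nzchar(raw$reference_label),
                             raw$reference_label, "unknown"),
    stringsAsFactors = FALSE
  )
  validate_cohort(out)
  out
}

#' @rdname read_encounters
#' @param cohort a validated cohort data.frame.
#' @export
write_encounters <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  out <- cohort
  out$age <- ifelse(is.na(out$age), "", as.character(out$age))
  out$date <- ifelse(is.na(out$date), "", format(out$date, "%Y-%m-%d"))
  out$reference_label <- ifelse(out$reference_label == "unknown", "",
                                out$reference_label)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Construct a phenotype algorithm
#'
#' A phenotype algorithm is a boolean combination of code-list clauses. Each
#' clause names an encounter field (`"dx"` for diagnostic codes, `"proc"`
#' for procedural codes) and a [code_list()]; a clause is satisfied when any
#' pattern in its list matches any code in that field. Clauses are combined
#' with `"ALL"` (conjunction) or `"ANY"` (disjunction).
#'
#' @param name algorithm name.
#' @param combiner `"ALL"` or `"ANY"`.
#' @param clauses a list of clauses, each `list(field =, code_list =)`.
#' @return an object of class `phenotype_algorithm`.
#' @export
phenotype_algorithm <- function(name, combiner, clauses) {
  if (!combiner %in% c("ALL", "ANY")) {
    abort_config("combiner must be ALL or ANY")
  }
  if (length(clauses) < 1L) abort_config("need at least one clause")
  for (cl in clauses) {
    if (!cl$field %in% c("dx", "proc")) {
      abort_config("clause field must be dx or proc")
    }
    if (!inherits(cl$code_list, "code_list")) {
      abort_config("clause code_list must be a code_list")
    }
    sys <- cl$code_list$system
    if (cl$field == "dx" && !sys %in% c("ICD10", "ICD9")) {
      abort_config("dx clauses pair with ICD systems")
    }
    if (cl$field == "proc" && sys != "CCI") {
      abort_config("proc clauses pair with CCI")
    }
  }
  structure(list(name = name, combiner = combiner, clauses = clauses),
            class = "phenotype_algorithm")
}

#' @export
print.phenotype_algorithm <- function(x, ...) {
  cat(sprintf("<phenotype_algorithm> %s: %s of\n", x$name, x$combiner))
  for (cl in x$clauses) {
    cat(sprintf("  - any %s code in list '%s' (%s, %d patterns)\n",
                cl$field, cl$code_list$name, cl$code_list$system,
                nrow(cl$code_list$patterns)))
  }
  invisible(x)
}

#' The three ESS-CRS model variants
#'
#' * `model1` — any chronic-rhinosinusitis ICD-10 diagnostic code;
#' * `model2` — any endoscopic-sinus-surgery CCI procedural code;
#' * `model3` — both (the final model): at least one CRS diagnostic code
#'   AND at least one ESS procedural code on the encounter.
#'
#' @return a named list of three [phenotype_algorithm()]s.
#' @export
model_catalog <- function() {
  lists <- builtin_code_lists()
  dx_clause <- list(field = "dx", code_list = lists$crs_icd10)
  proc_clause <- list(field = "proc", code_list = lists$ess_cci)
  list(
    model1 = phenotype_algorithm("model1", "ANY", list(dx_clause)),
    model2 = phenotype_algorithm("model2", "ANY", list(proc_clause)),
    model3 = phenotype_algorithm("model3", "ALL", list(dx_clause, proc_clause))
  )
}

#' Classify a single encounter
#'
#' @param encounter a list or one-row data.frame with `dx_codes` and
#'   `proc_codes` (character vectors of canonical codes, or `";"`-joined
#'   strings).
#' @param algorithm a [phenotype_algorithm()].
#' @return `"case"` or `"control"`.
#' @export
classify_encounter <- function(encounter, algorithm) {
  get_codes <- function(field) {
    v <- encounter[[if (field == "dx") "dx_codes" else "proc_codes"]]
    if (is.null(v)) return(character(0))
    v <- unlist(v, use.names = FALSE)
    if (length(v) == 1L && grepl(";", v, fixed = TRUE)) {
      v <- split_codes(v)[[1]]
    }
    v[!is.na(v) & nzchar(v)]
  }
  sat <- vapply(algorithm$clauses, function(cl) {
    any_match(cl$code_list, get_codes(cl$field))
  }, logical(1))
  hit <- if (algorithm$combiner == "ALL") all(sat) else any(sat)
  if (hit) "case" else "control"
}

#' Apply a phenotype algorithm to a cohort
#'
#' Vectorized classification of every encounter; equivalent to elementwise
#' [classify_encounter()] with order preserved.
#'
#' @param cohort a validated cohort data.frame.
#' @param algorithm a [phenotype_algorithm()].
#' @return data.frame with columns `encounter_id` and `label`
#'   (`"case"`/`"control"`).
#' @export
apply_algorithm <- function(cohort, algorithm) {
  cohort <- validate_cohort(cohort)
  if (nrow(cohort) == 0L) {
    return(data.frame(encounter_id = character(0), label = character(0),
                      stringsAsFactors = FALSE))
  }
  sat <- vapply(algorithm$clauses, function(cl) {
    field <- if (cl$field == "dx") cohort$dx_codes else cohort$proc_codes
    match_code_strings(field, cl$code_list)
  }, logical(nrow(cohort)))
  sat <- matrix(sat, nrow = nrow(cohort))
  hit <- if (algorithm$combiner == "ALL") {
    rowSums(sat) == ncol(sat)
  } else {
    rowSums(sat) > 0
  }
  data.frame(encounter_id = cohort$encounter_id,
             label = ifelse(hit, "case", "control"),
             stringsAsFactors = FALSE)
}

#' Restrict a cohort to adults
#'
#' Keeps encounters with `age >= min_age`. Encounters with missing age are
#' retained with a warning: the age restriction was an eligibility rule of
#' the chart review, not part of the coded model, so unknown-age encounters
#' are not silently dropped.
#'
#' @param cohort a cohort data.frame.
#' @param min_age minimum age in years (inclusive).
#' @return the filtered cohort.
#' @export
filter_adults <- function(cohort, min_age = 18) {
  cohort <- validate_cohort(cohort)
  assert_scalar_number(min_age, "min_age", lower = 0)
  n_missing <- sum(is.na(cohort$age))
  if (n_missing > 0) {
    warning(sprintf("%d encounters have missing age; retained", n_missing))
  }
  keep <- is.na(cohort$age) | cohort$age >= min_age
  cohort[keep, , drop = FALSE]
}

#' Read / write phenotype algorithms as JSON
#'
#' Dialect: `{"name": ..., "combiner": "ALL|ANY", "clauses": [{"field":
#' "dx|proc", "code_list": "<list name>"}]}`. Code-list names are resolved
#' against [builtin_code_lists()] plus any extra lists supplied.
#'
#' @param path file path.
#' @param code_lists named list of [code_list()]s available for resolution,
#'   in addition to the built-ins.
#' @return `read_algorithm()` returns a [phenotype_algorithm()].
#' @export
read_algorithm <- function(path, code_lists = list()) {
  if (!file.exists(path)) abort_config(sprintf("no such file: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$name) || is.null(x$combiner) || is.null(x$clauses)) {
    abort_config("algorithm JSON needs fields name, combiner, clauses")
  }
  available <- c(code_lists, builtin_code_lists())
  clauses <- lapply(x$clauses, function(cl) {
    ref <- cl$code_list
    if (is.null(available[[ref]])) {
      abort_config(sprintf("unknown code list '%s' in algorithm '%s'",
                           ref, x$name))
    }
    list(field = cl$field, code_list = available[[ref]])
  })
  phenotype_algorithm(x$name, x$combiner, clauses)
}

#' @rdname read_algorithm
#' @param algorithm a [phenotype_algorithm()].
#' @export
write_algorithm <- function(algorithm, path) {
  payload <- list(
    name = algorithm$name,
    combiner = algorithm$combiner,
    clauses = lapply(algorithm$clauses, function(cl) {
      list(field = cl$field, code_list = cl$code_list$name)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
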