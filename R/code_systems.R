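#' Administrative code systems
#'
#' Codes are drawn from three systems: `"ICD10"` (diagnoses, e.g. `"J32.0"`),
#' `"ICD9"` (legacy diagnoses, e.g. `"473.2"`) and `"CCI"` (Canadian
#' Classification of Health Interventions procedures, e.g. `"1.EU.52.^^"`,
#' where `"^^"` marks a wildcard qualifier group covering a whole family of
#' interventions).
#'
#' @name code-systems
NULL

CODE_SYSTEMS <- c("ICD10", "ICD9", "CCI")

check_system <- function(system) {
  if (!is.character(system) || length(system) != 1L ||
      !(system %in% CODE_SYSTEMS)) {
    abort_config(sprintf("unknown code system; must be one of %s",
                         paste(CODE_SYSTEMS, collapse = ", ")))
  }
  system
}

#' Normalize a raw administrative code
#'
#' Uppercases the code and strips dots and whitespace, so that the dotted
#' display forms used in code books (`"J32.0"`, `"1.EU.52.^^"`) and the
#' undotted forms found in extracts (`"J320"`, `"1EU52AB"`) compare equal.
#' Wildcard groups (`"^^"`) are preserved.
#'
#' @param raw character vector of codes as printed/stored.
#' @param system one of `"ICD10"`, `"ICD9"`, `"CCI"`.
#' @return character vector of canonical codes (uppercase, no dots).
#' @examples
#' normalize_code("J32.0", "ICD10")      # "J320"
#' normalize_code("1.EU.52.^^", "CCI")   # "1EU52^^"
#' @export
normalize_code <- function(raw, system = "ICD10") {
  check_system(system)
  if (!is.character(raw)) abort_input("codes must be character")
  out <- gsub("[.[:space:]]", "", toupper(trimws(raw)))
  if (any(!nzchar(out))) abort_input("invalid code: empty after normalization")
  out
}

#' Construct a code pattern
#'
#' A pattern is either a concrete code, a hierarchical parent rubric
#' (`"J32"` matches `"J32.0"`, `"J32.4"`, ...), or a CCI wildcard family
#' (`"1.EU.52.^^"` matches any qualifier completion such as `"1EU52AB"`).
#' Matching is prefix-based in both cases: a code matches when it starts
#' with the pattern's canonical text up to the first wildcard group.
#'
#' @param raw code as printed (may contain dots and `"^^"` groups).
#' @param system code system of the pattern.
#' @return an object of class `code_pattern` with fields `system`, `raw`,
#'   `canonical`, `wildcard_prefix` and `is_wildcard`.
#' @examples
#' code_pattern("1.EU.52.^^", "CCI")
#' @export
code_pattern <- function(raw, system = "ICD10") {
  check_system(system)
  if (length(raw) != 1L) abort_config("`raw` must be a single code")
  canonical <- normalize_code(raw, system)
  structure(
    list(
      system = system,
      raw = raw,
      canonical = canonical,
      wildcard_prefix = sub("\\^.*$", "", canonical),
      is_wildcard = grepl("^^", canonical, fixed = TRUE)
    ),
    class = "code_pattern"
  )
}

#' @export
print.code_pattern <- function(x, ...) {
  cat(sprintf("<code_pattern> %s [%s]%s\n", x$raw, x$system,
              if (x$is_wildcard) sprintf(" wildcard, prefix %s", x$wildcard_prefix) else ""))
  invisible(x)
}

#' Test whether a pattern matches a code
#'
#' Vectorized over `code`. A non-wildcard pattern matches any code that
#' starts with its canonical text (hierarchical prefix rule); a wildcard
#' pattern matches any code that starts with the text before the first
#' wildcard group.
#'
#' @param pattern a [code_pattern()].
#' @param code character vector of canonical codes (see [normalize_code()]).
#' @return logical vector.
#' @examples
#' code_matches(code_pattern("J32"), "J324")              # TRUE
#' code_matches(code_pattern("1.EU.52.^^", "CCI"), "1EU52AB")  # TRUE
#' @export
code_matches <- function(pattern, code) {
  if (!inherits(pattern, "code_pattern")) abort_config("`pattern` must be a code_pattern")
  startsWith(code, pattern$wildcard_prefix)
}

#' Construct a code list
#'
#' An ordered, deduplicated collection of patterns in one system, used as a
#' clause of a phenotype algorithm. Duplicate canonical patterns are stored
#' once (set semantics: duplicates cannot change any-match results).
#'
#' @param name list name.
#' @param system shared code system of all patterns.
#' @param codes character vector of raw codes as printed.
#' @return an object of class `code_list` with a `patterns` data.frame
#'   (columns `raw`, `canonical`, `wildcard_prefix`, `is_wildcard`).
#' @export
code_list <- function(name, system, codes) {
  check_system(system)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort_config("`name` must be a non-empty string")
  }
  canonical <- normalize_code(codes, system)
  keep <- !duplicated(canonical)
  patterns <- data.frame(
    raw = codes[keep],
    canonical = canonical[keep],
    wildcard_prefix = sub("\\^.*$", "", canonical[keep]),
    is_wildcard = grepl("^^", canonical[keep], fixed = TRUE),
    stringsAsFactors = FALSE
  )
  structure(list(name = name, system = system, patterns = patterns),
            class = "code_list")
}

#' @export
print.code_list <- function(x, ...) {
  cat(sprintf("<code_list> %s [%s]: %d patterns\n", x$name, x$system,
              nrow(x$patterns)))
  cat(" ", paste(x$patterns$raw, collapse = ", "), "\n")
  invisible(x)
}

#' Test whether any pattern in a list matches any code
#'
#' @param list a [code_list()].
#' @param codes character vector of canonical codes; an empty vector never
#'   matches.
#' @return `TRUE` if some pattern matches some code.
#' @export
any_match <- function(list, codes) {
  if (!inherits(list, "code_list")) abort_config("`list` must be a code_list")
  if (length(codes) == 0L) return(FALSE)
  for (p in list$patterns$wildcard_prefix) {
    if (any(startsWith(codes, p))) return(TRUE)
  }
  FALSE
}

# Vectorized any-match over ";"-joined code strings, used on whole cohorts.
match_code_strings <- function(code_strings, list) {
  codes <- split_codes(code_strings)
  idx <- rep.int(seq_along(codes), lengths(codes))
  flat <- unlist(codes, use.names = FALSE)
  res <- logical(length(code_strings))
  if (length(flat) == 0L) return(res)
  hit <- logical(length(flat))
  for (p in list$patterns$wildcard_prefix) {
    hit <- hit | startsWith(flat, p)
  }
  res[unique(idx[hit])] <- TRUE
  res
}

#' Built-in ESS-CRS code lists
#'
#' The three code lists of the ESS-CRS phenotype: chronic-rhinosinusitis
#' diagnoses in ICD-10 (`crs_icd10`: the J32 chronic sinusitis and J33 nasal
#' polyp families) and ICD-9 (`crs_icd9`: 473.x and 471.x), and endoscopic
#' sinus surgery procedures in CCI (`ess_cci`: therapeutic interventions on
#' the ethmoidal, sphenoidal, maxillary, frontal and paranasal sinuses —
#' drainage, destruction, repair, partial and radical excision families).
#' The ICD-9 list is carried for users defining analogous algorithms on
#' legacy data; the shipped models use only ICD-10 and CCI.
#'
#' @return a named list of three [code_list()] objects:
#'   `crs_icd10`, `crs_icd9`, `ess_cci`.
#' @export
builtin_code_lists <- function() {
  list(
    crs_icd10 = code_list("crs_icd10", "ICD10", c(
      "J32", "J32.0", "J32.1", "J32.2", "J32.3", "J32.4", "J32.8", "J32.9",
      "J33", "J33.0", "J33.1", "J33.8", "J33.9"
    )),
    crs_icd9 = code_list("crs_icd9", "ICD9", c(
      "473", "473.0", "473.1", "473.2", "473.3", "473.8", "473.9",
      "471", "471.0", "471.1", "471.8", "471.9"
    )),
    ess_cci = code_list("ess_cci", "CCI", c(
      "1.EU.^^.^^", "1.EU.52.^^", "1.EU.87.^^",
      "1.EV.^^.^^", "1.EV.52.^^", "1.EV.87.^^",
      "1.EW.^^.^^", "1.EW.52.^^",
      "1.EX.^^", "1.EX.52.^^", "1.EX.59.^^", "1.EX.80.^^", "1.EX.87.^^",
      "1.EY.^^.^^", "1.EY.87.^^", "1.EY.91.^^"
    ))
  )
}

#' Read / write code lists as JSON
#'
#' The JSON dialect is `{"name": ..., "system": "ICD10|ICD9|CCI",
#' "codes": [raw strings]}`; a file may hold one object or an array of them.
#'
#' @param path file path.
#' @return `read_code_lists()` returns a named list of [code_list()]s.
#' @export
read_code_lists <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("no such file: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(x$name)) x <- list(x)
  out <- lapply(x, function(cl) {
    if (is.null(cl$name) || is.null(cl$system) || is.null(cl$codes)) {
      abort_input("code list JSON needs fields name, system, codes")
    }
    code_list(cl$name, cl$system, unlist(cl$codes))
  })
  names(out) <- vapply(out, function(cl) cl$name, character(1))
  out
}

#' @rdname read_code_lists
#' @param lists a [code_list()] or list of them.
#' @export
write_code_lists <- function(lists, path) {
  if (inherits(lists, "code_list")) lists <- list(lists)
  payload <- lapply(unname(lists), function(cl) {
    list(name = cl$name, system = cl$system, codes = cl$patterns$raw)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
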