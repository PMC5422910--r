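#' Joint code-presence fixtures
#'
#' A fixture fixes, for each reference stratum (case / control), how many
#' encounters carry both a CRS diagnostic and an ESS procedural code, a
#' diagnostic code only, a procedural code only, or neither. Realizing a
#' fixture yields a cohort whose confusion tables under the three model
#' variants are fully determined by these counts — no randomness in the
#' labels, only in the concrete codes, ids and ordering.
#'
#' @param cases,controls named numeric vectors with elements `both`,
#'   `dx_only`, `proc_only`, `neither` (non-negative integers).
#' @param year_label free-text label for the cohort period (e.g.
#'   `"2011-2012"`); used to pick encounter dates when it parses as a year
#'   or year range.
#' @return an object of class `joint_count_fixture`.
#' @export
joint_count_fixture <- function(cases, controls, year_label = "") {
  strata <- c("both", "dx_only", "proc_only", "neither")
  for (nm in c("cases", "controls")) {
    v <- get(nm)
    if (!all(strata %in% names(v))) {
      abort_config(sprintf("`%s` needs named counts: %s", nm,
                           paste(strata, collapse = ", ")))
    }
    v <- v[strata]
    if (any(!is.finite(v)) || any(v < 0) || any(v != round(v))) {
      abort_config(sprintf("`%s` counts must be non-negative integers", nm))
    }
  }
  structure(list(cases = cases[strata], controls = controls[strata],
                 year_label = year_label),
            class = "joint_count_fixture")
}

#' @export
print.joint_count_fixture <- function(x, ...) {
  cat(sprintf("<joint_count_fixture> %s\n",
              if (nzchar(x$year_label)) x$year_label else "(unlabelled)"))
  m <- rbind(cases = x$cases, controls = x$controls)
  m <- cbind(m, total = rowSums(m))
  print(m)
  invisible(x)
}

# Expected confusion table of the final (both-codes) model on a realized
# fixture; pure arithmetic, no realization needed.
fixture_confusion <- function(fixture) {
  confusion_table(
    tp = unname(fixture$cases["both"]),
    fp = unname(fixture$controls["both"]),
    fn = sum(fixture$cases[c("dx_only", "proc_only", "neither")]),
    tn = sum(fixture$controls[c("dx_only", "proc_only", "neither")])
  )
}

#' Solve joint code-presence counts from printed model summaries
#'
#' Reconstructs the integer joint distribution of code presence from the
#' published three-model comparison: the final model's full 2x2 table plus
#' each single-clause model's sensitivity and PPV rounded to one decimal.
#' For each of the diagnostic-only and procedural-only models it searches
#' exhaustively over admissible integer (TP, FP) pairs — TP between the
#' final model's TP and the reference case total, FP bounded by the PPV
#' constraint — keeping pairs whose percentages reproduce the printed
#' values under round-half-up to one decimal. Errors if no pair or more
#' than one pair survives.
#'
#' @param model_summaries data.frame with columns `model` (`"model1"`,
#'   `"model2"`, optionally `"model3"`), `sensitivity_pct`, `ppv_pct`
#'   (percentages to 1 decimal).
#' @param reference_totals named vector `c(cases =, controls =)`.
#' @param final_model_table the final model's [confusion_table()].
#' @return a [joint_count_fixture()].
#' @param year_label passed through to the fixture.
#' @export
solve_joint_counts <- function(model_summaries, reference_totals,
                               final_model_table, year_label = "") {
  stopifnot(inherits(final_model_table, "confusion_table"))
  need <- c("model", "sensitivity_pct", "ppv_pct")
  if (!is.data.frame(model_summaries) ||
      !all(need %in% names(model_summaries))) {
    abort_config("model_summaries needs columns model, sensitivity_pct, ppv_pct")
  }
  cases <- reference_totals[["cases"]]
  controls <- reference_totals[["controls"]]
  if (cases <= 0 || controls <= 0) abort_config("reference totals must be positive")
  t3 <- final_model_table
  if (t3$tp + t3$fn != cases || t3$fp + t3$tn != controls) {
    abort_input("final model table margins disagree with reference totals")
  }

  # consistency check: model3's printed summary, if given, must match the table
  row3 <- model_summaries[model_summaries$model == "model3", ]
  if (nrow(row3) == 1) {
    if (round_half_up(100 * t3$tp / cases, 1) != row3$sensitivity_pct ||
        round_half_up(100 * t3$tp / (t3$tp + t3$fp), 1) != row3$ppv_pct) {
      abort_input("final model summary inconsistent with its 2x2 table")
    }
  }

  solve_model <- function(sens_pct, ppv_pct, label) {
    if (sens_pct > 100 || ppv_pct > 100 || sens_pct < 0 || ppv_pct < 0) {
      abort_input(sprintf(
        "%s: infeasible summary (sensitivity %.1f%%, PPV %.1f%%)",
        label, sens_pct, ppv_pct))
    }
    # monotonicity: the conjunctive final model's cases are a subset of each
    # single-clause model's, so TP >= t3$tp and FP >= t3$fp
    hits <- list()
    for (TP in seq(t3$tp, cases)) {
      if (round_half_up(100 * TP / cases, 1) != sens_pct) next
      # PPV bound: FP <= TP * (100/ppv_lo - 1); add slack for rounding
      fp_max <- if (ppv_pct > 0) ceiling(TP * (100 / max(ppv_pct - 0.05, 1e-9) - 1)) else controls
      for (FP in seq(t3$fp, min(fp_max, controls))) {
        if (round_half_up(100 * TP / (TP + FP), 1) == ppv_pct) {
          hits[[length(hits) + 1]] <- c(TP = TP, FP = FP)
        }
      }
    }
    if (length(hits) == 0) {
      abort_input(sprintf(
        "%s: no integer (TP, FP) reproduces sensitivity %.1f%% and PPV %.1f%% given totals (%d cases, %d controls)",
        label, sens_pct, ppv_pct, cases, controls))
    }
    if (length(hits) > 1) {
      abort_input(sprintf("%s: summary is ambiguous (%d integer solutions)",
                          label, length(hits)))
    }
    hits[[1]]
  }

  get_row <- function(model) {
    row <- model_summaries[model_summaries$model == model, ]
    if (nrow(row) != 1) abort_config(sprintf("missing summary row for %s", model))
    row
  }
  r1 <- get_row("model1")
  r2 <- get_row("model2")
  m1 <- solve_model(r1$sensitivity_pct, r1$ppv_pct, "model1")
  m2 <- solve_model(r2$sensitivity_pct, r2$ppv_pct, "model2")

  case_counts <- c(both = t3$tp,
                   dx_only = unname(m1["TP"]) - t3$tp,
                   proc_only = unname(m2["TP"]) - t3$tp,
                   neither = NA)
  case_counts["neither"] <- cases - sum(case_counts[1:3])
  ctrl_counts <- c(both = t3$fp,
                   dx_only = unname(m1["FP"]) - t3$fp,
                   proc_only = unname(m2["FP"]) - t3$fp,
                   neither = NA)
  ctrl_counts["neither"] <- controls - sum(ctrl_counts[1:3])
  if (case_counts["neither"] < 0 || ctrl_counts["neither"] < 0) {
    abort_input("solved per-model counts exceed the stratum totals")
  }
  joint_count_fixture(case_counts, ctrl_counts, year_label)
}

#' The published derivation-cohort confusion structure
#'
#' Convenience wrappers around the printed derivation-period results:
#' `derivation_model_summaries()` returns the three-model comparison
#' (sensitivity / PPV percentages), `derivation_confusion()` the final
#' model's 2x2 table (333/16/14/184,991 over 347 cases and 185,007
#' controls), and `derivation_fixture()` the joint fixture solved from
#' them via [solve_joint_counts()].
#'
#' @return see above.
#' @export
derivation_fixture <- function() {
  solve_joint_counts(
    derivation_model_summaries(),
    c(cases = 347, controls = 185007),
    derivation_confusion(),
    year_label = "2011-2012"
  )
}

#' @rdname derivation_fixture
#' @export
derivation_confusion <- function() confusion_table(333, 16, 14, 184991)

#' @rdname derivation_fixture
#' @export
derivation_model_summaries <- function() {
  data.frame(
    model = c("model1", "model2", "model3"),
    sensitivity_pct = c(96.5, 96.8, 96.0),
    ppv_pct = c(93.3, 93.3, 95.4),
    stringsAsFactors = FALSE
  )
}

#' The published internal-validation confusion structure
#'
#' The validation-year review set: all 192 model-predicted cases plus 200
#' sampled predicted controls, 392 encounters in all, with final-model
#' cells (tp = 186, fp = 6, fn = 2, tn = 198). Only the final model's 2x2
#' table is published for this period, so the within-stratum code-presence
#' split is chosen, not solved: the 2 false-negative cases are realized as
#' diagnostic-code-only encounters (they must be predicted controls), the
#' 198 true controls as neither-code encounters.
#'
#' @return a [joint_count_fixture()] over the 392 sampled encounters.
#' @export
validation_year_fixture <- function() {
  joint_count_fixture(
    cases = c(both = 186, dx_only = 2, proc_only = 0, neither = 0),
    controls = c(both = 6, dx_only = 0, proc_only = 0, neither = 198),
    year_label = "2013"
  )
}

# Concrete code pools for realization. Matching pools are leaf codes /
# explicit qualifier completions of the built-in lists; filler pools are
# codes from unrelated chapters and intervention families that match no
# built-in pattern (asserted by test).
realization_pools <- function() {
  list(
    dx_match = c("J320", "J321", "J322", "J323", "J324", "J328", "J329",
                 "J330", "J331", "J338", "J339"),
    proc_match = c("1EU52AA", "1EU87AA", "1EV52AA", "1EV87AA", "1EW52AA",
                   "1EX52AA", "1EX59AA", "1EX80AA", "1EX87AA",
                   "1EY87AA", "1EY91AA"),
    dx_filler = c("I10", "E119", "K219", "M545", "N390", "H6690", "S0250"),
    proc_filler = c("1FE87AA", "1GJ76AA", "1NM87AA", "1OT59AA", "1SQ52AA")
  )
}

fixture_date_range <- function(year_label) {
  years <- suppressWarnings(as.integer(regmatches(
    year_label, gregexpr("[0-9]{4}", year_label))[[1]]))
  years <- years[!is.na(years)]
  if (length(years) == 0) years <- c(2011L, 2012L)
  c(as.Date(sprintf("%d-01-01", min(years))),
    as.Date(sprintf("%d-12-31", max(years))))
}

#' Realize a synthetic cohort from a joint-count fixture
#'
#' Emits exactly the fixture's number of encounters per stratum. Encounters
#' in a "dx present" stratum receive one CRS ICD-10 leaf code drawn
#' uniformly; "proc present" strata one concrete qualifier completion of
#' the ESS CCI families; absent fields receive a non-matching filler code
#' so that negative space exercises the matcher. Ages are drawn 18-90,
#' dates uniformly inside the fixture's period, and the output order is
#' shuffled. Labels depend only on the presence strata, so the three-model
#' confusion tables are identical for every seed.
#'
#' @param fixture a [joint_count_fixture()].
#' @param seed integer seed (mandatory; the RNG state is set).
#' @return a cohort data.frame (see \link{encounter-cohort}).
#' @export
realize_cohort <- function(fixture, seed) {
  stopifnot(inherits(fixture, "joint_count_fixture"))
  assert_scalar_number(seed, "seed")
  set.seed(seed)
  pools <- realization_pools()
  n_total <- sum(fixture$cases) + sum(fixture$controls)
  if (n_total == 0) return(empty_cohort())

  strata <- expand.grid(
    pattern = c("both", "dx_only", "proc_only", "neither"),
    label = c("case", "control"),
    stringsAsFactors = FALSE
  )
  strata$n <- c(fixture$cases, fixture$controls)
  pattern <- rep(strata$pattern, strata$n)
  label <- rep(strata$label, strata$n)

  has_dx <- pattern %in% c("both", "dx_only")
  has_proc <- pattern %in% c("both", "proc_only")
  dx <- ifelse(has_dx,
               sample(pools$dx_match, n_total, replace = TRUE),
               sample(pools$dx_filler, n_total, replace = TRUE))
  proc <- ifelse(has_proc,
                 sample(pools$proc_match, n_total, replace = TRUE),
                 sample(pools$proc_filler, n_total, replace = TRUE))

  dates <- fixture_date_range(fixture$year_label)
  cohort <- data.frame(
    encounter_id = sprintf("E%07d", seq_len(n_total)),
    patient_id = sprintf("P%07d", seq_len(n_total)),
    age = sample(18:90, n_total, replace = TRUE),
    date = dates[1] + sample.int(as.integer(dates[2] - dates[1]) + 1L,
                                 n_total, replace = TRUE) - 1L,
    dx_codes = dx,
    proc_codes = proc,
    reference_label = label,
    stringsAsFactors = FALSE
  )
  cohort <- cohort[sample.int(n_total), , drop = FALSE]
  rownames(cohort) <- NULL
  cohort
}

#' Generate a cohort from free presence probabilities
#'
#' Each encounter draws CRS-diagnostic-code and ESS-procedural-code
#' presence from its reference stratum's probabilities. By default the two
#' draws are independent; `dependence` in `[0, 1]` mixes in a comonotone
#' coupling (the same uniform drives both draws with that probability),
#' inducing positive within-encounter correlation between diagnostic and
#' procedural coding.
#'
#' @param n_cases,n_controls stratum sizes.
#' @param p_dx_given_case,p_proc_given_case,p_dx_given_control,p_proc_given_control
#'   presence probabilities in `[0, 1]`.
#' @param seed integer seed (mandatory).
#' @param dependence mixture weight of the comonotone component.
#' @return a cohort data.frame.
#' @export
parametric_generate <- function(n_cases, n_controls,
                                p_dx_given_case, p_proc_given_case,
                                p_dx_given_control, p_proc_given_control,
                                seed, dependence = 0) {
  assert_scalar_number(n_cases, "n_cases", lower = 0)
  assert_scalar_number(n_controls, "n_controls", lower = 0)
  for (nm in c("p_dx_given_case", "p_proc_given_case",
               "p_dx_given_control", "p_proc_given_control", "dependence")) {
    assert_scalar_number(get(nm), nm, lower = 0, upper = 1)
  }
  assert_scalar_number(seed, "seed")
  set.seed(seed)
  n <- n_cases + n_controls
  if (n == 0) return(empty_cohort())
  label <- rep(c("case", "control"), c(n_cases, n_controls))
  p_dx <- ifelse(label == "case", p_dx_given_case, p_dx_given_control)
  p_proc <- ifelse(label == "case", p_proc_given_case, p_proc_given_control)
  u1 <- stats::runif(n)
  u2 <- stats::runif(n)
  shared <- stats::runif(n) < dependence
  u2[shared] <- u1[shared]
  has_dx <- u1 < p_dx
  has_proc <- u2 < p_proc

  pools <- realization_pools()
  dx <- ifelse(has_dx,
               sample(pools$dx_match, n, replace = TRUE),
               sample(pools$dx_filler, n, replace = TRUE))
  proc <- ifelse(has_proc,
                 sample(pools$proc_match, n, replace = TRUE),
                 sample(pools$proc_filler, n, replace = TRUE))
  cohort <- data.frame(
    encounter_id = sprintf("E%07d", seq_len(n)),
    patient_id = sprintf("P%07d", seq_len(n)),
    age = sample(18:90, n, replace = TRUE),
    date = as.Date("2011-01-01") + sample.int(730L, n, replace = TRUE) - 1L,
    dx_codes = dx,
    proc_codes = proc,
    reference_label = label,
    stringsAsFactors = FALSE
  )
  cohort <- cohort[sample.int(n), , drop = FALSE]
  rownames(cohort) <- NULL
  cohort
}

#' Draw an internal-validation review set
#'
#' Implements the internal-validation sampling design: every encounter the
#' algorithm labels a case, plus a seeded uniform random sample (without
#' replacement) of `n_controls` encounters the algorithm labels controls.
#'
#' @param cohort a cohort data.frame.
#' @param algorithm a [phenotype_algorithm()].
#' @param n_controls number of predicted controls to sample.
#' @param seed integer seed (mandatory).
#' @return the sampled subset of `cohort` (row order: original order).
#' @export
sample_validation_cohort <- function(cohort, algorithm, n_controls, seed) {
  cohort <- validate_cohort(cohort)
  assert_scalar_number(n_controls, "n_controls", lower = 0)
  assert_scalar_number(seed, "seed")
  labels <- apply_algorithm(cohort, algorithm)
  is_case <- labels$label == "case"
  ctrl_idx <- which(!is_case)
  if (n_controls > length(ctrl_idx)) {
    abort_input(sprintf(
      "requested %d controls but only %d encounters are model-identified controls",
      n_controls, length(ctrl_idx)))
  }
  set.seed(seed)
  keep <- sort(c(which(is_case),
                 if (n_controls > 0) sample(ctrl_idx, n_controls) else integer(0)))
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove encounters lost to record linkage
#'
#' Emulates linkage attrition: removes a seeded random subset of
#' `n_lost_cases` reference cases and `n_lost_controls` reference controls.
#'
#' @param cohort a cohort data.frame.
#' @param n_lost_cases,n_lost_controls counts to remove per stratum.
#' @param seed integer seed (mandatory).
#' @return the reduced cohort.
#' @export
apply_attrition <- function(cohort, n_lost_cases, n_lost_controls, seed) {
  cohort <- validate_cohort(cohort)
  assert_scalar_number(n_lost_cases, "n_lost_cases", lower = 0)
  assert_scalar_number(n_lost_controls, "n_lost_controls", lower = 0)
  assert_scalar_number(seed, "seed")
  case_idx <- which(cohort$reference_label == "case")
  ctrl_idx <- which(cohort$reference_label == "control")
  if (n_lost_cases > length(case_idx) || n_lost_controls > length(ctrl_idx)) {
    abort_input("attrition exceeds available encounters in a stratum")
  }
  set.seed(seed)
  drop <- c(if (n_lost_cases > 0) sample(case_idx, n_lost_cases) else integer(0),
            if (n_lost_controls > 0) sample(ctrl_idx, n_lost_controls) else integer(0))
  out <- if (length(drop)) cohort[-drop, , drop = FALSE] else cohort
  rownames(out) <- NULL
  out
}

#' Read / write joint-count fixtures (JSON or YAML)
#'
#' Dialect: `{"year_label": ..., "cases": {"both": ..., "dx_only": ...,
#' "proc_only": ..., "neither": ...}, "controls": {...}}`.
#'
#' @param path file path; format chosen by extension (`.json` vs
#'   `.yaml`/`.yml`).
#' @return `read_fixture()` returns a [joint_count_fixture()].
#' @export
read_fixture <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("no such file: %s", path))
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(x$cases) || is.null(x$controls)) {
    abort_input("fixture file needs fields cases and controls")
  }
  joint_count_fixture(unlist(x$cases), unlist(x$controls),
                      x$year_label %||% "")
}

#' @rdname read_fixture
#' @param fixture a [joint_count_fixture()].
#' @export
write_fixture <- function(fixture, path) {
  stopifnot(inherits(fixture, "joint_count_fixture"))
  payload <- list(year_label = fixture$year_label,
                  cases = as.list(fixture$cases),
                  controls = as.list(fixture$controls))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(payload, path)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
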