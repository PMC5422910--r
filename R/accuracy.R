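#' 2x2 confusion tables
#'
#' The validation unit of a phenotype algorithm: predicted case/control
#' status cross-tabulated against the reference standard.
#'
#' @param tp,fp,fn,tn non-negative integer counts (true positive, false
#'   positive, false negative, true negative).
#' @return an object of class `confusion_table`.
#' @examples
#' confusion_table(333, 16, 14, 184991)
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    abort_input("confusion counts must be non-negative integers")
  }
  structure(as.list(counts), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$tp + x$fn,
                x$fp, x$tn, x$fp + x$tn,
                x$tp + x$fp, x$fn + x$tn, x$tp + x$fp + x$fn + x$tn),
              nrow = 3,
              dimnames = list(
                c("predicted case", "predicted control", "total"),
                c("reference case", "reference control", "total")))
  cat("<confusion_table>\n")
  print(format(m, big.mark = ","), quote = FALSE)
  invisible(x)
}

#' Build a confusion table from predicted and reference labels
#'
#' @param predicted data.frame with columns `encounter_id` and `label`
#'   (e.g. from [apply_algorithm()]), or a character vector of labels.
#' @param reference same shape as `predicted`; labels must be `"case"` or
#'   `"control"` (no `"unknown"`). When both are data.frames they are
#'   joined on `encounter_id` and must cover the same id set.
#' @return a [confusion_table()].
#' @export
build_confusion <- function(predicted, reference) {
  as_label_frame <- function(x, what) {
    if (is.data.frame(x)) {
      if (!all(c("encounter_id", "label") %in% names(x))) {
        abort_input(sprintf("%s needs columns encounter_id, label", what))
      }
      x[, c("encounter_id", "label")]
    } else {
      data.frame(encounter_id = as.character(seq_along(x)), label = x,
                 stringsAsFactors = FALSE)
    }
  }
  p <- as_label_frame(predicted, "predicted")
  r <- as_label_frame(reference, "reference")
  if (!all(r$label %in% c("case", "control"))) {
    abort_input("reference labels must be case or control")
  }
  if (!all(p$label %in% c("case", "control"))) {
    abort_input("predicted labels must be case or control")
  }
  if (nrow(p) != nrow(r) || !setequal(p$encounter_id, r$encounter_id)) {
    abort_input("predicted and reference must cover the same encounter ids")
  }
  r <- r[match(p$encounter_id, r$encounter_id), ]
  pc <- p$label == "case"
  rc <- r$label == "case"
  confusion_table(tp = sum(pc & rc), fp = sum(pc & !rc),
                  fn = sum(!pc & rc), tn = sum(!pc & !rc))
}

#' Confusion table of an algorithm against a cohort's reference labels
#'
#' Convenience wrapper: classifies the cohort and cross-tabulates against
#' its `reference_label` column (which must not contain `"unknown"`).
#'
#' @param cohort a validated cohort data.frame with reference labels.
#' @param algorithm a [phenotype_algorithm()].
#' @return a [confusion_table()].
#' @export
confusion_from_cohort <- function(cohort, algorithm) {
  cohort <- validate_cohort(cohort)
  build_confusion(
    apply_algorithm(cohort, algorithm),
    data.frame(encounter_id = cohort$encounter_id,
               label = cohort$reference_label, stringsAsFactors = FALSE)
  )
}

#' Binomial proportion confidence interval
#'
#' @param successes,n counts, `0 <= successes <= n`, `n > 0`.
#' @param method `"clopper_pearson"` (exact, beta-quantile form; the
#'   default), `"wilson"` (score) or `"wald"` (normal approximation,
#'   clipped to `[0, 1]`).
#' @param level coverage probability in (0, 1).
#' @return an object of class `confidence_interval` with fields `lower`,
#'   `upper`, `level`, `method`.
#' @examples
#' ci_proportion(333, 347)  # about (0.933, 0.978)
#' @export
ci_proportion <- function(successes, n,
                          method = c("clopper_pearson", "wilson", "wald"),
                          level = 0.95) {
  method <- match.arg(method)
  assert_scalar_number(level, "level")
  if (level <= 0 || level >= 1) abort_config("level must be in (0, 1)")
  assert_scalar_number(n, "n", lower = 1)
  assert_scalar_number(successes, "successes", lower = 0, upper = n)
  x <- successes
  alpha <- 1 - level
  p <- x / n
  bounds <- switch(method,
    clopper_pearson = c(
      if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1),
      if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
    ),
    wilson = {
      z <- stats::qnorm(1 - alpha / 2)
      centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
      half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
      c(centre - half, centre + half)
    },
    wald = {
      z <- stats::qnorm(1 - alpha / 2)
      half <- z * sqrt(p * (1 - p) / n)
      pmin(pmax(c(p - half, p + half), 0), 1)
    }
  )
  structure(list(lower = bounds[1], upper = bounds[2],
                 level = level, method = method),
            class = "confidence_interval")
}

#' @export
print.confidence_interval <- function(x, ...) {
  cat(sprintf("<%g%% CI, %s> (%g, %g)\n", 100 * x$level, x$method,
              x$lower, x$upper))
  invisible(x)
}

#' Likelihood ratios of a confusion table
#'
#' `lr_positive` = sensitivity / (1 - specificity); returns `Inf` when
#' `fp = 0` (perfect specificity with at least one true positive).
#' `lr_negative` = (1 - sensitivity) / specificity. Both are computed from
#' unrounded proportions; `NA` when undefined (no reference controls).
#'
#' @param t a [confusion_table()].
#' @return a single numeric ratio.
#' @export
lr_positive <- function(t) {
  stopifnot(inherits(t, "confusion_table"))
  if (t$tn + t$fp == 0 || t$tp + t$fn == 0) return(NA_real_)
  se <- t$tp / (t$tp + t$fn)
  sp <- t$tn / (t$tn + t$fp)
  if (sp == 1) {
    if (se > 0) Inf else NA_real_
  } else {
    se / (1 - sp)
  }
}

#' @rdname lr_positive
#' @export
lr_negative <- function(t) {
  stopifnot(inherits(t, "confusion_table"))
  if (t$tn + t$fp == 0 || t$tp + t$fn == 0) return(NA_real_)
  sp <- t$tn / (t$tn + t$fp)
  if (sp == 0) return(NA_real_)
  se <- t$tp / (t$tp + t$fn)
  (1 - se) / sp
}

#' Log-method confidence interval for a likelihood ratio
#'
#' The standard log-transform (Simel-type) interval:
#' `exp(log(LR) +/- z * SE)` with
#' `SE(log LR+) = sqrt(1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn))` and, for the
#' negative ratio, `SE(log LR-) = sqrt(1/fn - 1/(tp+fn) + 1/tn - 1/(fp+tn))`.
#' Undefined (all-`NA` bounds, flagged via the `defined` field) when a
#' required cell is zero.
#'
#' @param t a [confusion_table()].
#' @param which `"positive"` or `"negative"`.
#' @param level coverage probability.
#' @return a `confidence_interval` with an extra logical field `defined`.
#' @export
ci_likelihood_ratio <- function(t, which = c("positive", "negative"),
                                level = 0.95) {
  which <- match.arg(which)
  stopifnot(inherits(t, "confusion_table"))
  if (level <= 0 || level >= 1) abort_config("level must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - level) / 2)
  n1 <- t$tp + t$fn
  n0 <- t$fp + t$tn
  if (which == "positive") {
    lr <- lr_positive(t)
    ok <- t$tp > 0 && t$fp > 0 && n1 > 0 && n0 > 0
    se_log <- if (ok) sqrt(1 / t$tp - 1 / n1 + 1 / t$fp - 1 / n0) else NA_real_
  } else {
    lr <- lr_negative(t)
    ok <- t$fn > 0 && t$tn > 0 && n1 > 0 && n0 > 0
    se_log <- if (ok) sqrt(1 / t$fn - 1 / n1 + 1 / t$tn - 1 / n0) else NA_real_
  }
  bounds <- if (ok && is.finite(lr) && lr > 0) {
    exp(log(lr) + c(-1, 1) * z * se_log)
  } else {
    c(NA_real_, NA_real_)
  }
  structure(list(lower = bounds[1], upper = bounds[2], level = level,
                 method = "log_lr", defined = ok && is.finite(lr) && lr > 0),
            class = "confidence_interval")
}

#' Positive predictive value at a hypothetical prevalence
#'
#' Bayes' theorem: `PPV = Se * prev / (Se * prev + (1 - Sp) * (1 - prev))`.
#' Lets users project the predictive value of a validated algorithm onto a
#' centre with a different case mix. For the table's own prevalence this
#' reproduces `tp / (tp + fp)` exactly.
#'
#' @param sens,spec,prev proportions in `[0, 1]`.
#' @return a proportion, or `NA` when the denominator is zero.
#' @export
ppv_at_prevalence <- function(sens, spec, prev) {
  for (nm in c("sens", "spec", "prev")) {
    assert_scalar_number(get(nm), nm, lower = 0, upper = 1)
  }
  denom <- sens * prev + (1 - spec) * (1 - prev)
  if (denom == 0) return(NA_real_)
  sens * prev / denom
}

#' Full diagnostic accuracy report for a confusion table
#'
#' Computes sensitivity, specificity, positive and negative predictive
#' value and prevalence with binomial confidence intervals, and the
#' positive and negative likelihood ratios with log-method intervals.
#' Statistics are carried as unrounded proportions; rounding happens only
#' in the formatted display strings (see [format_report()]). A statistic
#' with a zero denominator is reported as `NA` (undefined), never as 0.
#'
#' @param t a [confusion_table()].
#' @param ci_method method for proportion intervals, see [ci_proportion()].
#' @param level coverage probability.
#' @return an object of class `accuracy_report`: a list of per-statistic
#'   entries (`estimate`, `ci`, `formatted`) plus the table and settings.
#' @examples
#' accuracy_report(confusion_table(333, 16, 14, 184991))
#' @export
accuracy_report <- function(t, ci_method = "clopper_pearson", level = 0.95) {
  stopifnot(inherits(t, "confusion_table"))
  total <- t$tp + t$fp + t$fn + t$tn
  if (total == 0) abort_input("empty confusion table")
  prop_stat <- function(x, n) {
    if (n == 0) {
      list(estimate = NA_real_, ci = NULL)
    } else {
      list(estimate = x / n, ci = ci_proportion(x, n, ci_method, level))
    }
  }
  stats <- list(
    sensitivity = prop_stat(t$tp, t$tp + t$fn),
    specificity = prop_stat(t$tn, t$tn + t$fp),
    ppv         = prop_stat(t$tp, t$tp + t$fp),
    npv         = prop_stat(t$tn, t$tn + t$fn),
    prevalence  = prop_stat(t$tp + t$fn, total),
    lr_positive = list(estimate = lr_positive(t),
                       ci = ci_likelihood_ratio(t, "positive", level)),
    lr_negative = list(estimate = lr_negative(t),
                       ci = ci_likelihood_ratio(t, "negative", level))
  )
  out <- structure(list(table = t, statistics = stats,
                        ci_method = ci_method, level = level),
                   class = "accuracy_report")
  out$formatted <- format_report(out)
  out
}

is_ratio_stat <- function(name) name %in% c("lr_positive", "lr_negative")

#' Format a value the way the validation tables print it
#'
#' Proportions are shown as percentages: 1 decimal, except values that
#' would round to 100.0 are shown as `"100"` and percentages below 1 keep
#' 2 decimals (so a 0.19% prevalence is not flattened to 0.2). Ratios use
#' magnitude-dependent precision: `>= 100` nearest integer with a
#' thousands separator, `[1, 100)` 1 decimal, `< 1` 2 decimals.
#' Half-way values round away from zero, matching the tables.
#'
#' @param x numeric value.
#' @param type `"percent"` or `"ratio"`.
#' @return a display string (`"undefined"` for `NA`, `"Inf"` for an
#'   infinite ratio).
#' @export
format_stat <- function(x, type = c("percent", "ratio")) {
  type <- match.arg(type)
  if (is.na(x)) return("undefined")
  if (type == "percent") {
    pct <- 100 * x
    if (x >= 0.9995) return("100")
    if (pct < 1) return(sprintf("%.2f", round_half_up(pct, 2)))
    return(sprintf("%.1f", round_half_up(pct, 1)))
  }
  if (is.infinite(x)) return("Inf")
  if (x >= 100) {
    return(formatC(round_half_up(x, 0), format = "d", big.mark = ","))
  }
  if (x >= 1) return(sprintf("%.1f", round_half_up(x, 1)))
  sprintf("%.2f", round_half_up(x, 2))
}

#' Display strings for every statistic of a report
#'
#' @param r an [accuracy_report()].
#' @return named character vector: for each statistic, the formatted point
#'   estimate, and `<name>_ci` entries of the form `"(lower-upper)"`.
#' @export
format_report <- function(r) {
  stopifnot(inherits(r, "accuracy_report"))
  out <- character(0)
  for (nm in names(r$statistics)) {
    s <- r$statistics[[nm]]
    type <- if (is_ratio_stat(nm)) "ratio" else "percent"
    out[nm] <- format_stat(s$estimate, type)
    ci <- s$ci
    out[paste0(nm, "_ci")] <- if (is.null(ci) || is.na(ci$lower)) {
      "undefined"
    } else {
      sprintf("(%s-%s)", format_stat(ci$lower, type), format_stat(ci$upper, type))
    }
  }
  out
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> %g%% CIs (%s; log method for LRs)\n",
              100 * x$level, x$ci_method))
  f <- x$formatted
  for (nm in names(x$statistics)) {
    unit <- if (is_ratio_stat(nm)) "" else "%"
    cat(sprintf("  %-12s %s%s %s\n", nm, f[nm], unit, f[paste0(nm, "_ci")]))
  }
  invisible(x)
}

#' Write an accuracy report to JSON and CSV
#'
#' JSON carries the raw (unrounded) estimates, CI bounds and methods; CSV
#' has one row per statistic: `name, estimate, lower, upper, formatted`.
#'
#' @param r an [accuracy_report()].
#' @param json_path,csv_path output paths; `NULL` to skip one of them.
#' @return invisibly, the report as a data.frame (the CSV layout).
#' @export
write_report <- function(r, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(r, "accuracy_report"))
  rows <- do.call(rbind, lapply(names(r$statistics), function(nm) {
    s <- r$statistics[[nm]]
    data.frame(
      name = nm,
      estimate = s$estimate,
      lower = if (is.null(s$ci)) NA_real_ else s$ci$lower,
      upper = if (is.null(s$ci)) NA_real_ else s$ci$upper,
      formatted = r$formatted[[nm]],
      stringsAsFactors = FALSE
    )
  }))
  if (!is.null(json_path)) {
    payload <- list(
      confusion = unclass(r$table),
      ci_method = r$ci_method,
      level = r$level,
      statistics = lapply(seq_len(nrow(rows)), function(i) {
        as.list(rows[i, c("name", "estimate", "lower", "upper", "formatted")])
      })
    )
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  }
  if (!is.null(csv_path)) {
    utils::write.csv(rows, csv_path, row.names = FALSE, na = "")
  }
  invisible(rows)
}
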