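# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (startsWith-based matching, qbeta intervals).

# Regex-based matching oracle: a pattern matches a code iff the code is an
# extension of the pattern text before the first wildcard group.
oracle_matches <- function(raw_pattern, code) {
  canonical <- gsub("[.[:space:]]", "", toupper(raw_pattern))
  prefix <- sub("\\^.*$", "", canonical)
  grepl(paste0("^", prefix), code)
}

# Naive per-encounter classifier: double loop over clauses, patterns and
# codes with substring comparison.
oracle_classify <- function(dx, proc, algorithm) {
  clause_sat <- vapply(algorithm$clauses, function(cl) {
    codes <- if (cl$field == "dx") dx else proc
    pats <- cl$code_list$patterns$wildcard_prefix
    hit <- FALSE
    for (p in pats) {
      for (cd in codes) {
        if (nchar(cd) >= nchar(p) && substr(cd, 1, nchar(p)) == p) hit <- TRUE
      }
    }
    hit
  }, logical(1))
  sat <- if (algorithm$combiner == "ALL") all(clause_sat) else any(clause_sat)
  if (sat) "case" else "control"
}

# Clopper-Pearson oracle: bisection on the binomial tail probabilities,
# independent of the beta-quantile form used by the implementation.
oracle_clopper_pearson <- function(x, n, level = 0.95, tol = 1e-9) {
  alpha <- 1 - level
  bisect <- function(f, lo, hi) {
    for (i in 1:80) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  lower <- if (x == 0) 0 else {
    bisect(function(p) stats::pbinom(x - 1, n, p, lower.tail = FALSE) - alpha / 2,
           0, 1)
  }
  upper <- if (x == n) 1 else {
    bisect(function(p) alpha / 2 - stats::pbinom(x, n, p), 0, 1)
  }
  c(lower, upper)
}

# Random small cohort over a mix of matching and non-matching codes.
random_cohort <- function(n, seed) {
  set.seed(seed)
  dx_pool <- c("J320", "J321", "J339", "J32", "I10", "K219", "J45", "")
  proc_pool <- c("1EU52AB", "1EX59ZZ", "1EY91AA", "1FE87AA", "1GJ76AA", "")
  pick <- function(pool) {
    vapply(seq_len(n), function(i) {
      k <- sample(0:2, 1)
      paste(sample(setdiff(pool, ""), k), collapse = ";")
    }, character(1))
  }
  data.frame(
    encounter_id = sprintf("E%04d", seq_len(n)),
    patient_id = sprintf("P%04d", seq_len(n)),
    age = sample(c(NA, 16:90), n, replace = TRUE),
    date = as.Date("2011-06-01") + seq_len(n),
    dx_codes = pick(dx_pool),
    proc_codes = pick(proc_pool),
    reference_label = sample(c("case", "control"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
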