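# The two published 2x2 tables: derivation period and internal validation.
t_deriv <- confusion_table(333, 16, 14, 184991)
t_valid <- confusion_table(186, 6, 2, 198)

test_that("build_confusion cross-tabulates labels and conserves counts", {
  set.seed(8)
  for (n in c(10, 57, 200)) {
    ref <- sample(c("case", "control"), n, replace = TRUE, prob = c(0.3, 0.7))
    pred <- ifelse(stats::runif(n) < 0.8, ref,
                   ifelse(ref == "case", "control", "case"))
    ids <- sprintf("E%03d", seq_len(n))
    ct <- build_confusion(data.frame(encounter_id = ids, label = pred),
                          data.frame(encounter_id = sample(ids), label =
                                       ref[match(sample(ids), ids)]))
    # conservation regardless of row order on either side
    ct <- build_confusion(data.frame(encounter_id = ids, label = pred),
                          data.frame(encounter_id = ids, label = ref))
    expect_equal(ct$tp + ct$fp + ct$fn + ct$tn, n)
    expect_equal(ct$tp, sum(pred == "case" & ref == "case"))
    expect_equal(ct$fn, sum(pred == "control" & ref == "case"))
  }
  ct <- build_confusion(c("case", "control"), c("case", "control"))
  expect_equal(c(ct$fp, ct$fn), c(0, 0))
  expect_error(build_confusion(c("case"), c("unknown")),
               class = "phenoval_input_error")
  expect_error(
    build_confusion(data.frame(encounter_id = "A", label = "case"),
                    data.frame(encounter_id = "B", label = "case")),
    class = "phenoval_input_error")
})

test_that("point estimates reproduce the published derivation statistics", {
  r <- accuracy_report(t_deriv)
  expect_equal(r$statistics$sensitivity$estimate, 333 / 347)
  expect_equal(r$statistics$specificity$estimate, 184991 / 185007)
  expect_equal(r$statistics$ppv$estimate, 333 / 349)
  expect_equal(r$statistics$prevalence$estimate, 347 / 185354)
  expect_equal(r$formatted[["sensitivity"]], "96.0")
  expect_equal(r$formatted[["specificity"]], "100")
  expect_equal(r$formatted[["ppv"]], "95.4")
  expect_equal(r$formatted[["prevalence"]], "0.19")
  expect_equal(r$formatted[["lr_positive"]], "11,096")
  expect_equal(r$formatted[["lr_negative"]], "0.04")
})

test_that("point estimates reproduce the published validation statistics", {
  r <- accuracy_report(t_valid)
  expect_equal(r$statistics$ppv$estimate, 0.96875)
  expect_equal(r$formatted[["sensitivity"]], "98.9")
  expect_equal(r$formatted[["specificity"]], "97.1")
  expect_equal(r$formatted[["ppv"]], "96.9")
  expect_equal(r$formatted[["lr_positive"]], "33.6")
  expect_equal(r$formatted[["lr_negative"]], "0.01")
})

test_that("zero denominators yield undefined statistics, not zero", {
  r <- accuracy_report(confusion_table(0, 0, 5, 5))
  expect_equal(r$statistics$sensitivity$estimate, 0)
  expect_true(is.na(r$statistics$ppv$estimate))
  expect_equal(r$formatted[["ppv"]], "undefined")
  # perfect specificity with hits: LR+ is an infinity sentinel
  expect_true(is.infinite(lr_positive(confusion_table(5, 0, 0, 5))))
  expect_equal(format_stat(Inf, "ratio"), "Inf")
  # no reference controls: both LRs undefined
  expect_true(is.na(lr_positive(confusion_table(5, 0, 5, 0))))
})

test_that("Clopper-Pearson agrees with tail-probability bisection for n <= 50", {
  for (n in c(1, 2, 5, 10, 17, 25, 33, 50)) {
    for (x in 0:n) {
      got <- ci_proportion(x, n, "clopper_pearson")
      want <- oracle_clopper_pearson(x, n)
      expect_equal(c(got$lower, got$upper), want, tolerance = 1e-6,
                   info = sprintf("x=%d n=%d", x, n))
    }
  }
})

test_that("Wilson agrees with the score interval of prop.test", {
  for (case in list(c(3, 10), c(40, 60), c(333, 347), c(0, 20), c(20, 20))) {
    got <- ci_proportion(case[1], case[2], "wilson")
    want <- stats::prop.test(case[1], case[2], correct = FALSE)$conf.int
    expect_equal(c(got$lower, got$upper), as.numeric(want), tolerance = 1e-9)
  }
})

test_that("proportion CIs respect boundaries, contain the estimate, widen with level", {
  expect_equal(ci_proportion(0, 20)$lower, 0)
  expect_equal(ci_proportion(20, 20)$upper, 1)
  set.seed(5)
  for (i in 1:40) {
    n <- sample(1:400, 1); x <- sample(0:n, 1)
    for (m in c("clopper_pearson", "wilson", "wald")) {
      ci90 <- ci_proportion(x, n, m, level = 0.90)
      ci99 <- ci_proportion(x, n, m, level = 0.99)
      expect_true(ci90$lower >= 0 && ci90$upper <= 1)
      expect_true(ci90$lower <= x / n && x / n <= ci90$upper)
      expect_true(ci99$lower <= ci90$lower + 1e-12)
      expect_true(ci99$upper >= ci90$upper - 1e-12)
    }
  }
  expect_error(ci_proportion(5, 4), class = "phenoval_config_error")
  expect_error(ci_proportion(1, 4, level = 1), class = "phenoval_config_error")
})

test_that("the exact interval on the derivation sensitivity matches print precision", {
  ci <- ci_proportion(333, 347, "clopper_pearson")
  expect_equal(ci$lower, 0.932, tolerance = 0.002)
  expect_equal(ci$upper, 0.977, tolerance = 0.002)
})

test_that("log-method likelihood-ratio intervals reproduce the published bounds", {
  ci_p <- ci_likelihood_ratio(t_deriv, "positive")
  expect_equal(ci_p$lower, 6795, tolerance = 0.002)
  expect_equal(ci_p$upper, 18121, tolerance = 0.002)
  ci_n <- ci_likelihood_ratio(t_deriv, "negative")
  expect_equal(round(ci_n$lower, 2), 0.02)
  expect_equal(round(ci_n$upper, 2), 0.07)
  ci_v <- ci_likelihood_ratio(t_valid, "positive")
  expect_equal(round(ci_v$lower, 1), 15.3)
  expect_equal(round(ci_v$upper, 1), 74.0)
  # uninformative symmetric table: the interval straddles 1
  sym <- ci_likelihood_ratio(confusion_table(10, 10, 10, 10), "positive")
  expect_true(sym$lower < 1 && sym$upper > 1)
  # zero cell: undefined and flagged
  z <- ci_likelihood_ratio(confusion_table(5, 0, 2, 10), "positive")
  expect_false(z$defined)
  expect_true(is.na(z$lower))
})

test_that("likelihood-ratio CIs contain the point estimate", {
  set.seed(31)
  for (i in 1:25) {
    ct <- confusion_table(sample(1:200, 1), sample(1:50, 1),
                          sample(1:50, 1), sample(1:5000, 1))
    cp <- ci_likelihood_ratio(ct, "positive")
    expect_true(cp$lower <= lr_positive(ct) && lr_positive(ct) <= cp$upper)
    cn <- ci_likelihood_ratio(ct, "negative")
    expect_true(cn$lower <= lr_negative(ct) && lr_negative(ct) <= cn$upper)
  }
})

test_that("ppv_at_prevalence satisfies the Bayes identity on any table", {
  set.seed(17)
  for (i in 1:50) {
    ct <- confusion_table(sample(1:100, 1), sample(0:50, 1),
                          sample(0:50, 1), sample(1:10000, 1))
    se <- ct$tp / (ct$tp + ct$fn)
    sp <- ct$tn / (ct$tn + ct$fp)
    prev <- (ct$tp + ct$fn) / (ct$tp + ct$fp + ct$fn + ct$tn)
    expect_equal(ppv_at_prevalence(se, sp, prev), ct$tp / (ct$tp + ct$fp),
                 tolerance = 1e-12)
  }
  expect_equal(ppv_at_prevalence(0.5, 0.5, 1), 1)
  expect_equal(ppv_at_prevalence(0.9, 1.0, 0.001), 1)
  expect_true(is.na(ppv_at_prevalence(0, 1, 0.5)))
})

test_that("swapping predicted labels transposes the table as expected", {
  set.seed(23)
  for (i in 1:20) {
    n <- 80
    ref <- sample(c("case", "control"), n, replace = TRUE)
    pred <- sample(c("case", "control"), n, replace = TRUE)
    ids <- as.character(seq_len(n))
    orig <- build_confusion(data.frame(encounter_id = ids, label = pred),
                            data.frame(encounter_id = ids, label = ref))
    flipped <- ifelse(pred == "case", "control", "case")
    sw <- build_confusion(data.frame(encounter_id = ids, label = flipped),
                          data.frame(encounter_id = ids, label = ref))
    expect_equal(sw$tp, orig$fn)
    expect_equal(sw$fp, orig$tn)
    # sensitivity of the swapped table = miss rate of the original
    if (orig$tp + orig$fn > 0) {
      expect_equal(sw$tp / (sw$tp + sw$fn),
                   orig$fn / (orig$tp + orig$fn))
    }
  }
})

test_that("formatting follows the table display conventions", {
  expect_equal(format_stat(0.95965, "percent"), "96.0")
  expect_equal(format_stat(0.9999135, "percent"), "100")
  expect_equal(format_stat(0.99949, "percent"), "99.9")
  expect_equal(format_stat(347 / 185354, "percent"), "0.19")
  expect_equal(format_stat(11096.42, "ratio"), "11,096")
  expect_equal(format_stat(33.6383, "ratio"), "33.6")
  expect_equal(format_stat(0.04035, "ratio"), "0.04")
  expect_equal(format_stat(0.01096, "ratio"), "0.01")
  expect_equal(format_stat(NA_real_, "percent"), "undefined")
  # half-way values round away from zero
  expect_equal(format_stat(0.9345, "percent"), "93.5")
  expect_equal(format_stat(2.25, "ratio"), "2.3")
})

test_that("reports serialize to JSON and CSV", {
  r <- accuracy_report(t_valid)
  json_path <- withr::local_tempfile(fileext = ".json")
  csv_path <- withr::local_tempfile(fileext = ".csv")
  rows <- write_report(r, json_path, csv_path)
  expect_equal(rows$name[1], "sensitivity")
  expect_equal(rows$estimate[rows$name == "ppv"], 0.96875)
  back <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  expect_equal(back$confusion$tp, 186)
  expect_equal(back$statistics$estimate[back$statistics$name == "ppv"], 0.96875)
  csv_back <- utils::read.csv(csv_path)
  expect_equal(nrow(csv_back), 7)
})
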