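g_default <- default_guideline()

audit_one <- function(tsb, pt_given, ...) {
  rec <- make_record(tsb = tsb, pt_given = pt_given, ...)
  classify_treatment(rec, g_default)
}

test_that("treatment classification follows the chart-review definitions", {
  # thresholds for the helper's default term infant at 48 h, no risk
  pt_thr <- threshold_at(guideline_curve(g_default, "term_near_term",
                                         "phototherapy", "no_risk"), 48)
  expect_identical(audit_one(pt_thr + 1, pt_given = FALSE)$classification,
                   "under_treatment")
  expect_identical(audit_one(pt_thr - 1, pt_given = TRUE)$classification,
                   "over_treatment")
  expect_identical(audit_one(NA_real_, pt_given = TRUE)$classification,
                   "inappropriate")
  expect_identical(audit_one(NA_real_, pt_given = FALSE)$classification,
                   "unevaluable")
  expect_identical(audit_one(pt_thr + 1, pt_given = TRUE)$classification,
                   "correct")
  # correctly withholding treatment also counts as correct
  expect_identical(audit_one(pt_thr - 1, pt_given = FALSE)$classification,
                   "correct")
  # boundary: TSB exactly at the threshold indicates treatment
  expect_identical(audit_one(pt_thr, pt_given = TRUE)$classification, "correct")
  expect_identical(audit_one(pt_thr, pt_given = FALSE)$classification,
                   "under_treatment")
})

test_that("classification is exhaustive and mutually exclusive over the lattice", {
  pt_thr <- threshold_at(guideline_curve(g_default, "term_near_term",
                                         "phototherapy", "no_risk"), 48)
  tsb_states <- list(NA_real_, pt_thr - 2, pt_thr, pt_thr + 2)
  seen <- character(0)
  for (tsb in tsb_states) {
    for (pt in c(TRUE, FALSE)) {
      for (ex in c(TRUE, FALSE)) {
        cls <- classify_treatment(
          make_record(tsb = tsb, pt_given = pt, exchange_given = ex),
          g_default)$classification
        expect_length(cls, 1L)
        expect_true(cls %in% c("correct", "over_treatment", "under_treatment",
                               "inappropriate", "unevaluable"))
        seen <- c(seen, cls)
      }
    }
  }
  expect_setequal(unique(seen), c("correct", "over_treatment",
                                  "under_treatment", "inappropriate",
                                  "unevaluable"))
  # exchange transfusion never alters the four-way classification
  for (tsb in tsb_states) for (pt in c(TRUE, FALSE)) {
    a <- classify_treatment(make_record(tsb = tsb, pt_given = pt,
                                        exchange_given = TRUE), g_default)
    b <- classify_treatment(make_record(tsb = tsb, pt_given = pt,
                                        exchange_given = FALSE), g_default)
    expect_identical(a$classification, b$classification)
  }
})

test_that("epoch tabulation partitions evaluable records and reports the rest", {
  results <- list(
    audit_one(20, pt_given = TRUE, epoch = "pre"),          # correct
    audit_one(1, pt_given = TRUE, epoch = "pre"),           # over
    audit_one(20, pt_given = FALSE, epoch = "post"),        # under
    audit_one(NA_real_, pt_given = TRUE, epoch = "post"),   # inappropriate
    audit_one(NA_real_, pt_given = FALSE, epoch = "post")   # unevaluable
  )
  tab <- summarize_epochs(results)
  expect_identical(dim(tab), c(4L, 2L))
  expect_identical(sum(tab), 4L)
  expect_identical(attr(tab, "n_unevaluable"), 1L)
  expect_identical(unname(tab["correct", "pre"]), 1L)
  expect_identical(unname(tab["under_treatment", "post"]), 1L)

  single <- summarize_epochs(list(audit_one(20, pt_given = TRUE, epoch = "pre")))
  expect_identical(as.integer(single), c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L))
  expect_error(summarize_epochs(list(audit_one(NA_real_, pt_given = FALSE))),
               class = "bilinorm_domain_error")
})

test_that("the packaged epoch-comparison fixture carries the published counts", {
  fx <- bilinorm_fixtures()$table2
  expect_identical(unname(unclass(fx$classification)),
                   matrix(c(97L, 87L, 35L, 36L, 93L, 57L, 18L, 13L), ncol = 2))
  expect_identical(unname(unclass(fx$ga)),
                   matrix(c(137L, 118L, 89L, 92L), ncol = 2))
  expect_equal(colSums(fx$classification), c(pre = 255, post = 181))
  expect_equal(colSums(fx$bw), c(pre = 255, post = 181))
  expect_equal(colSums(fx$risk), c(pre = 255, post = 181))
})

test_that("pearson_chi_square matches an explicit O/E + survival-function oracle", {
  set.seed(19)
  for (i in 1:1000) {
    m <- random_table()
    got <- pearson_chi_square(m)
    want <- chisq_oracle(m)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$df, want$df)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
  }
})

test_that("epoch relabelling (column swap) leaves the test unchanged", {
  set.seed(23)
  for (i in 1:50) {
    m <- random_table()
    a <- pearson_chi_square(m)
    b <- pearson_chi_square(m[, 2:1])
    expect_equal(a$statistic, b$statistic)
    expect_equal(a$p_value, b$p_value)
  }
})

test_that("identical column proportions give statistic 0 and p 1; degenerate tables error", {
  r <- pearson_chi_square(matrix(c(10, 30, 5, 15), nrow = 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_error(pearson_chi_square(matrix(c(0, 5, 0, 7), nrow = 2)),
               class = "bilinorm_domain_error")
  expect_error(pearson_chi_square(matrix(c(3, 0, 4, 0), nrow = 2, byrow = TRUE)),
               class = "bilinorm_domain_error")
})

test_that("the published epoch comparison reproduces from the fixture counts", {
  fx <- bilinorm_fixtures()$table2
  expect_equal(round(pearson_chi_square(fx$correct)$p_value, 3), 0.006)
  expect_equal(round(pearson_chi_square(fx$inappropriate)$p_value, 3), 0.024)
  expect_equal(round(pearson_chi_square(fx$over)$p_value, 3), 0.566)
  expect_equal(round(pearson_chi_square(fx$under)$p_value, 3), 0.234)
  expect_equal(round(pearson_chi_square(fx$classification)$p_value, 3), 0.016)
  expect_equal(round(pearson_chi_square(fx$ga)$p_value, 3), 0.348)
  expect_equal(round(pearson_chi_square(fx$bw)$p_value, 3), 0.786)
  expect_equal(round(pearson_chi_square(fx$risk)$p_value, 3), 0.614)
})

test_that("two identical epochs give p = 1 throughout the comparison", {
  base <- list(
    list(tsb = 20, pt = TRUE, ga = 38, bw = 3000, risk = "none_declared"),
    list(tsb = 20, pt = TRUE, ga = 33, bw = 1200, risk = "other_illness"),
    list(tsb = 1, pt = TRUE, ga = 30, bw = 900, risk = "unknown"),
    list(tsb = 20, pt = FALSE, ga = 34, bw = 1800, risk = "haemolysis"),
    list(tsb = NA_real_, pt = TRUE, ga = 36, bw = 2600,
         risk = "abo_rh_incompatibility")
  )
  results <- list()
  for (ep in c("pre", "post")) {
    for (b in base) {
      results[[length(results) + 1L]] <-
        audit_one(b$tsb, pt_given = b$pt, ga = b$ga, bw = b$bw, risk = b$risk,
                  epoch = ep)
    }
  }
  cmp <- compare_epochs(results)
  for (t in cmp$tests) expect_equal(t$p_value, 1)
})

test_that("GA-band stratification splits the audit as requested", {
  results <- list(
    audit_one(20, pt_given = TRUE, ga = 33, bw = 2100, epoch = "pre"),
    audit_one(2, pt_given = TRUE, ga = 33, bw = 2100, epoch = "post"),
    audit_one(20, pt_given = TRUE, ga = 38, bw = 3000, epoch = "pre"),
    audit_one(20, pt_given = FALSE, ga = 38, bw = 3000, epoch = "post")
  )
  cmp <- compare_epochs(results, by_ga_band = TRUE)
  expect_named(cmp$ga_band, c("lt_35", "ge_35"))
  expect_identical(sum(cmp$ga_band$lt_35$classification), 2L)
  expect_identical(sum(cmp$ga_band$ge_35$classification), 2L)
})
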