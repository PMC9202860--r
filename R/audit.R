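#' @title Guideline-adherence chart audit
#' @description
#' The audit engine compares the treatment each infant actually received
#' with the treatment the guideline indicated at that record's TSB,
#' postnatal age, stratum and risk class, classifies each record as correct,
#' over-treatment, under-treatment or inappropriate treatment, tabulates the
#' classifications by study epoch (before/after introduction of the decision
#' tool) and compares epochs with uncorrected Pearson chi-square tests.
#'
#' Definitions: under-treatment = no treatment although the TSB is above the
#' phototherapy threshold; over-treatment = phototherapy although the TSB is
#' below the threshold; correct = agreement with the guideline in either
#' direction (treating when indicated, or withholding when not);
#' inappropriate = phototherapy given without any TSB measurement. Records
#' with neither a TSB measurement nor phototherapy cannot be assessed and
#' are reported separately as unevaluable.
#' @name adherence_audit
NULL

CLASSIFICATIONS <- c("correct", "over_treatment", "under_treatment", "inappropriate")
EPOCHS <- c("pre", "post")

#' Construct a treatment record for audit
#'
#' @param patient a [patient_record()]; its `tsb_value` may be `NA` when no
#'   TSB was measured.
#' @param pt_given was phototherapy administered?
#' @param exchange_given was an exchange transfusion administered? Recorded
#'   and reported, but the four-way classification is defined purely on the
#'   phototherapy threshold.
#' @param epoch `"pre"` or `"post"` (study epoch).
#' @param tsb_measured whether a TSB measurement exists; defaults to the
#'   presence of `tsb_value` in the patient record and must be consistent
#'   with it.
#' @return A `treatment_record`.
#' @export
treatment_record <- function(patient, pt_given, exchange_given = FALSE,
                             epoch = c("pre", "post"),
                             tsb_measured = !is.na(patient$tsb_mg_dl)) {
  stopifnot(inherits(patient, "patient_record"))
  epoch <- match.arg(epoch)
  if (!tsb_measured && !is.na(patient$tsb_mg_dl)) {
    stop_domain("tsb_measured = FALSE but the patient record carries a TSB value")
  }
  if (tsb_measured && is.na(patient$tsb_mg_dl)) {
    stop_domain("tsb_measured = TRUE but the patient record has no TSB value")
  }
  structure(
    list(patient = patient, tsb_measured = isTRUE(tsb_measured),
         pt_given = isTRUE(pt_given), exchange_given = isTRUE(exchange_given),
         epoch = epoch),
    class = "treatment_record"
  )
}

#' Classify one treatment record against the guideline
#'
#' Precedence: phototherapy without any TSB measurement is inappropriate
#' treatment; no measurement and no phototherapy is unevaluable; otherwise
#' the administered phototherapy is compared with the guideline indication
#' (TSB at or above the phototherapy threshold indicates treatment).
#'
#' @param record a [treatment_record()].
#' @param guideline a `guideline_table`.
#' @return An `audit_result` with `classification` (one of `"correct"`,
#'   `"over_treatment"`, `"under_treatment"`, `"inappropriate"`,
#'   `"unevaluable"`), the `record`, and the full `recommendation` where a
#'   TSB was available (`NULL` otherwise).
#' @export
classify_treatment <- function(record, guideline = default_guideline()) {
  stopifnot(inherits(record, "treatment_record"))
  if (!record$tsb_measured) {
    cls <- if (record$pt_given) "inappropriate" else "unevaluable"
    rec <- NULL
  } else {
    rec <- recommend(record$patient, guideline)
    indicated <- rec$tsb_mg_dl >= rec$pt_threshold
    cls <- if (indicated && record$pt_given) "correct"
      else if (!indicated && !record$pt_given) "correct"
      else if (!indicated && record$pt_given) "over_treatment"
      else "under_treatment"
  }
  structure(list(record = record, classification = cls, recommendation = rec),
            class = "audit_result")
}

#' Audit a whole cohort of treatment records
#'
#' @param records list of [treatment_record()]s.
#' @param guideline a `guideline_table`.
#' @return List of `audit_result`s.
#' @export
audit_cohort <- function(records, guideline = default_guideline()) {
  lapply(records, classify_treatment, guideline = guideline)
}

#' Construct a labelled r x 2 contingency table
#'
#' @param counts non-negative integer matrix with one column per epoch.
#' @param row_labels character row labels.
#' @param col_labels character column labels (default `"pre"`, `"post"`).
#' @return A `contingency_table` (a labelled integer matrix).
#' @export
contingency_table <- function(counts, row_labels = rownames(counts),
                              col_labels = c("pre", "post")) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_domain("contingency counts must be non-negative integers")
  }
  if (ncol(counts) != length(col_labels)) {
    stop_domain("counts must have one column per epoch label")
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(row_labels, col_labels)
  structure(counts, class = c("contingency_table", "matrix", "array"))
}

#' Tabulate audit classifications by epoch
#'
#' Builds the 4 x 2 classification-by-epoch table (correct, over-treatment,
#' under-treatment, inappropriate as rows; pre/post as columns). Evaluable
#' records partition into the four rows; unevaluable records are excluded
#' from the table and returned in the `"n_unevaluable"` attribute.
#'
#' @param results list of `audit_result`s containing at least one evaluable
#'   record; an epoch with no evaluable records yields a zero column, which
#'   the chi-square test subsequently rejects as degenerate.
#' @return A `contingency_table` with attribute `n_unevaluable`.
#' @export
summarize_epochs <- function(results) {
  cls <- vapply(results, function(r) r$classification, character(1))
  epoch <- vapply(results, function(r) r$record$epoch, character(1))
  keep <- cls != "unevaluable"
  if (!any(keep)) stop_domain("no evaluable records to tabulate")
  tab <- table(factor(cls[keep], levels = CLASSIFICATIONS),
               factor(epoch[keep], levels = EPOCHS))
  out <- contingency_table(unclass(tab), row_labels = CLASSIFICATIONS)
  attr(out, "n_unevaluable") <- sum(!keep)
  out
}

#' Uncorrected Pearson chi-square test on a contingency table
#'
#' Computes the Pearson statistic (sum over cells of (O-E)^2 / E with
#' expected counts from the row/column marginals), without Yates continuity
#' correction, and the p-value from the chi-square distribution with
#' (r-1)(c-1) degrees of freedom. Rows or columns whose marginal total is
#' zero make the expectation degenerate and raise an error. The
#' small-expected-count approximation warning is suppressed: audit tables
#' routinely contain sparse rows (e.g. rare risk factors) and the test is
#' reported as-is, matching standard practice for these summary tables.
#'
#' @param table a `contingency_table` or plain count matrix.
#' @return A `chisq_result` with `statistic`, `df`, `p_value`, `observed`
#'   and `expected`.
#' @export
pearson_chi_square <- function(table) {
  m <- as.matrix(unclass(table))
  if (any(m < 0)) stop_domain("counts must be non-negative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop_domain("degenerate table: a row or column total is zero")
  }
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop_domain("chi-square needs at least a 2 x 2 table")
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  structure(
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = unname(ht$p.value), observed = m,
         expected = unname(ht$expected)),
    class = "chisq_result"
  )
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square = %.4f, df = %d, p = %.3f\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

category_vs_rest <- function(tab, row) {
  rest <- colSums(tab) - tab[row, ]
  contingency_table(rbind(tab[row, ], rest),
                    row_labels = c(row, "other"), col_labels = colnames(tab))
}

demographic_tables <- function(results) {
  pats <- lapply(results, function(r) r$record$patient)
  epoch <- factor(vapply(results, function(r) r$record$epoch, character(1)),
                  levels = EPOCHS)
  ga <- factor(ifelse(vapply(pats, `[[`, numeric(1), "ga_weeks") < 35,
                      "lt_35", "ge_35"), levels = c("lt_35", "ge_35"))
  bw_g <- vapply(pats, `[[`, numeric(1), "bw_g")
  bw <- cut(bw_g, breaks = c(-Inf, 999, 1499, 2499, Inf),
            labels = c("lt_1000", "1000_1499", "1500_2499", "ge_2500"))
  risk <- vapply(pats, function(p) {
    rf <- p$risk_factors
    if ("abo_rh_incompatibility" %in% rf) "abo_rh_incompatibility"
    else if ("haemolysis" %in% rf) "haemolysis"
    else if (any(c("other_illness", "hypoalbuminemia") %in% rf)) "other_illness"
    else if ("none_declared" %in% rf) "none_declared"
    else "unknown"
  }, character(1))
  risk <- factor(risk, levels = c("abo_rh_incompatibility", "haemolysis",
                                  "other_illness", "none_declared", "unknown"))
  list(
    ga = contingency_table(unclass(table(ga, epoch)), levels(ga)),
    bw = contingency_table(unclass(table(bw, epoch)), levels(bw)),
    risk = contingency_table(unclass(table(risk, epoch)), levels(risk))
  )
}

drop_empty_rows <- function(tab) {
  keep <- rowSums(tab) > 0
  contingency_table(tab[keep, , drop = FALSE], rownames(tab)[keep], colnames(tab))
}

#' Full pre/post epoch comparison
#'
#' Produces the complete audit comparison: the overall 4 x 2
#' classification-by-epoch test, a 2 x 2 category-versus-rest test for each
#' of the four classifications, and demographic r x 2 tests (gestational age
#' below/at-or-above 35 weeks; birth-weight display bands <1000, 1000-1499,
#' 1500-2499, >=2500 g; five risk-factor categories). Demographic rows with
#' zero total are dropped before testing. Optionally the classification
#' table is additionally stratified by gestational-age band.
#'
#' @param results list of `audit_result`s.
#' @param by_ga_band also return per-GA-band (below / at-or-above 35 weeks)
#'   classification tables and tests?
#' @return An `epoch_comparison`: list with `classification` (the 4 x 2
#'   table), `tests` (named list of `chisq_result`s: `overall`, one per
#'   classification, `ga`, `bw`, `risk`), `n_unevaluable`, and optionally
#'   `ga_band` with per-band tables and tests.
#' @export
compare_epochs <- function(results, by_ga_band = FALSE) {
  tab <- summarize_epochs(results)
  tests <- list(overall = pearson_chi_square(drop_empty_rows(tab)))
  for (row in CLASSIFICATIONS) {
    if (sum(tab[row, ]) > 0) {
      tests[[row]] <- pearson_chi_square(category_vs_rest(tab, row))
    }
  }
  demo <- demographic_tables(results)
  for (d in c("ga", "bw", "risk")) {
    dt <- drop_empty_rows(demo[[d]])
    if (nrow(dt) >= 2L) tests[[d]] <- pearson_chi_square(dt)
  }
  out <- list(classification = tab, demographics = demo, tests = tests,
              n_unevaluable = attr(tab, "n_unevaluable"))
  if (by_ga_band) {
    ga_lt35 <- vapply(results, function(r) r$record$patient$ga_weeks < 35,
                      logical(1))
    out$ga_band <- lapply(
      stats::setNames(c(TRUE, FALSE), c("lt_35", "ge_35")),
      function(flag) {
        sub <- results[ga_lt35 == flag]
        st <- summarize_epochs(sub)
        list(classification = st,
             overall = pearson_chi_square(drop_empty_rows(st)))
      })
  }
  class(out) <- "epoch_comparison"
  out
}

#' @export
print.epoch_comparison <- function(x, ...) {
  cat("Epoch comparison (pre vs post)\n")
  n <- colSums(x$classification)
  cat(sprintf("  evaluable records: pre n = %d, post n = %d (unevaluable: %d)\n",
              n[1], n[2], x$n_unevaluable))
  for (row in rownames(x$classification)) {
    cnt <- x$classification[row, ]
    pct <- round_half_up(100 * cnt / n)
    p <- if (is.null(x$tests[[row]])) "   n/a" else
      sprintf("%.3f", x$tests[[row]]$p_value)
    cat(sprintf("  %-16s %3d (%2d%%)  %3d (%2d%%)   p = %s\n", row,
                cnt[1], pct[1], cnt[2], pct[2], p))
  }
  cat(sprintf("  overall classification p = %.3f\n", x$tests$overall$p_value))
  for (d in c("ga", "bw", "risk")) {
    if (!is.null(x$tests[[d]])) {
      cat(sprintf("  %s bands p = %.3f\n", d, x$tests[[d]]$p_value))
    }
  }
  invisible(x)
}
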