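#' Packaged study-summary fixtures
#'
#' The published evaluation of the decision tool reports two summary tables
#' that this package carries as fixtures so its statistics can be
#' reproduced end to end: (1) the technology-acceptance questionnaire count
#' table (22 items over four sections, 43 respondents) and (2) the
#' chart-review epoch comparison (255 records before and 181 after the
#' tool's introduction) — the four-way treatment classification plus the
#' gestational-age, birth-weight and risk-factor marginals. The underlying
#' per-infant charts are not public; only these printed counts are.
#'
#' @return A list with elements:
#' \describe{
#'   \item{table1}{a [likert_table()] of the questionnaire counts.}
#'   \item{table2}{a list of [contingency_table()]s: `classification`
#'     (4 x 2), `ga` (2 x 2), `bw` (4 x 2), `risk` (5 x 2), and one 2 x 2
#'     category-versus-rest table per classification (`correct`, `over`,
#'     `under`, `inappropriate`).}
#' }
#' @examples
#' fx <- bilinorm_fixtures()
#' pearson_chi_square(fx$table2$classification)
#' @export
bilinorm_fixtures <- function() {
  list(table1 = fixture_table1(), table2 = fixture_table2())
}

fixture_table2 <- function() {
  classification <- contingency_table(
    rbind(correct = c(97L, 93L), over_treatment = c(87L, 57L),
          under_treatment = c(35L, 18L), inappropriate = c(36L, 13L)))
  vs_rest <- lapply(stats::setNames(nm = rownames(classification)),
                    function(row) category_vs_rest(classification, row))
  list(
    classification = classification,
    ga = contingency_table(rbind(lt_35 = c(137L, 89L), ge_35 = c(118L, 92L))),
    bw = contingency_table(rbind(lt_1000 = c(2L, 1L), `1000_1499` = c(22L, 20L),
                                 `1500_2499` = c(149L, 99L),
                                 ge_2500 = c(82L, 61L))),
    risk = contingency_table(rbind(
      abo_rh_incompatibility = c(2L, 1L), haemolysis = c(0L, 1L),
      other_illness = c(144L, 106L), none_declared = c(86L, 53L),
      unknown = c(23L, 20L))),
    correct = vs_rest$correct,
    over = vs_rest$over_treatment,
    under = vs_rest$under_treatment,
    inappropriate = vs_rest$inappropriate
  )
}

fixture_table1 <- function() {
  row <- function(section, code, text, n1, n2, n3, n4, n5, n6, n7) {
    data.frame(section = section, code = code, text = text, n1 = n1, n2 = n2,
               n3 = n3, n4 = n4, n5 = n5, n6 = n6, n7 = n7,
               stringsAsFactors = FALSE)
  }
  items <- rbind(
    row("usefulness", "A.1", "Helps quickly decide the need of phototherapy in jaundiced babies", 0, 0, 1, 5, 1, 12, 24),
    row("usefulness", "A.2", "Helps to be more aware of acute bilirubin encephalopathy", 0, 0, 0, 6, 2, 11, 24),
    row("usefulness", "A.3", "Helps to be more aware of kernicterus", 0, 0, 0, 4, 2, 12, 25),
    row("usefulness", "A.4", "Helps improve hyperbilirubinemia management", 0, 0, 0, 4, 3, 12, 24),
    row("usefulness", "A.5", "Helps improve communication, information and education to parents", 0, 0, 0, 6, 2, 13, 22),
    row("usefulness", "A.6", "Helps improve follow-up of hyperbilirubinemia babies", 0, 0, 0, 4, 2, 14, 23),
    row("ease_of_use", "B.1", "Learning to use the tool is easy", 0, 0, 0, 6, 6, 10, 21),
    row("ease_of_use", "B.2", "Easy to get the information wanted", 0, 0, 0, 8, 4, 10, 21),
    row("ease_of_use", "B.3", "Clear and understandable", 0, 0, 2, 4, 2, 15, 20),
    row("ease_of_use", "B.4", "Flexible to use", 0, 0, 2, 3, 7, 10, 21),
    row("ease_of_use", "B.5", "Easy to become skillful in using it", 0, 0, 2, 3, 6, 13, 19),
    row("ease_of_use", "B.6", "Easy to use", 0, 0, 0, 5, 5, 11, 22),
    row("subjective_norm", "C.1", "Colleagues think the tool is important to you", 0, 0, 2, 6, 5, 12, 18),
    row("subjective_norm", "C.2", "Important to colleagues that you continue to use it", 0, 0, 1, 8, 4, 13, 17),
    row("subjective_norm", "C.3", "Would not really matter to colleagues if you stopped", 2, 2, 3, 9, 8, 7, 12),
    row("subjective_norm", "C.4", "Colleagues would expect you to continue to use it", 0, 1, 1, 6, 6, 13, 16),
    row("subjective_norm", "C.5", "No colleague would be surprised if you stopped", 0, 1, 3, 12, 5, 9, 13),
    row("subjective_norm", "C.6", "Colleagues would be disappointed if you stopped", 0, 2, 0, 13, 4, 11, 13),
    row("subjective_norm", "C.7", "Colleagues would make you feel guilty if you stopped", 0, 3, 1, 11, 7, 10, 11),
    row("intention", "D.1", "Intend to use the tool in the next months", 0, 0, 0, 5, 6, 14, 18),
    row("intention", "D.2", "Predict using the tool in the next months", 0, 0, 1, 6, 5, 12, 19),
    row("intention", "D.3", "Plan to use the tool in the next months", 0, 0, 1, 6, 4, 14, 18)
  )
  likert_table(items, n_respondents = 43L)
}
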