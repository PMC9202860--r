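#' @title Seven-point Likert questionnaire summaries
#' @description
#' Summaries for technology-acceptance-model (TAM) style questionnaires:
#' items grouped into perceived usefulness, perceived ease of use,
#' subjective norm and intention sections, each answered on a seven-point
#' scale from 1 (strongly disagree) to 7 (strongly agree). Agreement is, by
#' convention, answering 6 (agree) or 7 (strongly agree); displayed
#' percentages use half-up integer rounding.
#' @name questionnaire
NULL

LIKERT_SECTIONS <- c("usefulness", "ease_of_use", "subjective_norm", "intention")

#' Construct a validated Likert count table
#'
#' @param items data frame with columns `section` (one of
#'   `r paste0('"', LIKERT_SECTIONS, '"', collapse = ", ")`), `code` (item
#'   label, e.g. `"A.1"`), `text` (item wording) and `n1`..`n7` (response
#'   counts per level).
#' @param n_respondents number of respondents; every item's counts must sum
#'   to it.
#' @return A `likert_table`.
#' @export
likert_table <- function(items, n_respondents) {
  need <- c("section", "code", "text", paste0("n", 1:7))
  missing_cols <- setdiff(need, names(items))
  if (length(missing_cols)) {
    stop_parse("likert items missing column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  bad_sec <- setdiff(unique(items$section), LIKERT_SECTIONS)
  if (length(bad_sec)) stop_parse("unknown section(s): ",
                                  paste(bad_sec, collapse = ", "))
  counts <- as.matrix(items[, paste0("n", 1:7)])
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_validation("response counts must be non-negative integers")
  }
  sums <- rowSums(counts)
  off <- which(sums != n_respondents)
  if (length(off)) {
    stop_validation("item(s) whose counts do not sum to n_respondents: ",
                    paste(items$code[off], collapse = ", "))
  }
  structure(list(items = items, n_respondents = as.integer(n_respondents)),
            class = "likert_table")
}

likert_item <- function(table, code) {
  i <- match(code, table$items$code)
  if (is.na(i)) stop_domain("no questionnaire item with code '", code, "'")
  table$items[i, ]
}

#' Agreement rate for one questionnaire item
#'
#' The proportion of respondents answering within `agree_levels`
#' (default levels 6 and 7, i.e. agree or strongly agree).
#'
#' @param table a [likert_table()].
#' @param code item code (e.g. `"A.1"`).
#' @param agree_levels integer response levels counted as agreement.
#' @return List with `percent` (half-up integer for display),
#'   `percent_exact`, `n_agree` and `n`.
#' @export
agreement_rate <- function(table, code, agree_levels = c(6L, 7L)) {
  stopifnot(inherits(table, "likert_table"))
  if (any(!agree_levels %in% 1:7)) stop_domain("agree_levels must be within 1..7")
  item <- likert_item(table, code)
  n_agree <- sum(unlist(item[paste0("n", agree_levels)]))
  exact <- 100 * n_agree / table$n_respondents
  list(percent = round_half_up(exact), percent_exact = exact,
       n_agree = n_agree, n = table$n_respondents)
}

#' Per-level distribution of one questionnaire item
#'
#' @param table a [likert_table()].
#' @param code item code.
#' @return Data frame with `level`, `count`, `percent` (half-up integer)
#'   and `percent_exact`.
#' @export
item_distribution <- function(table, code) {
  stopifnot(inherits(table, "likert_table"))
  item <- likert_item(table, code)
  counts <- as.numeric(unlist(item[paste0("n", 1:7)]))
  exact <- 100 * counts / table$n_respondents
  data.frame(level = 1:7, count = counts,
             percent = round_half_up(exact), percent_exact = exact)
}

#' Per-section aggregates of a Likert table
#'
#' Pools the response counts of all items in each section and reports the
#' pooled level distribution and the pooled agreement rate.
#'
#' @param table a [likert_table()].
#' @param agree_levels integer levels counted as agreement (default 6, 7).
#' @return Data frame with one row per section: `section`, `n_items`,
#'   pooled `level1`..`level7` counts, `agreement_percent` (half-up) and
#'   `agreement_percent_exact`.
#' @export
section_summary <- function(table, agree_levels = c(6L, 7L)) {
  stopifnot(inherits(table, "likert_table"))
  out <- lapply(LIKERT_SECTIONS, function(sec) {
    sub <- table$items[table$items$section == sec, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    pooled <- colSums(as.matrix(sub[, paste0("n", 1:7)]))
    agree <- sum(pooled[agree_levels])
    exact <- 100 * agree / sum(pooled)
    df <- data.frame(section = sec, n_items = nrow(sub))
    df[paste0("level", 1:7)] <- as.list(pooled)
    df$agreement_percent <- round_half_up(exact)
    df$agreement_percent_exact <- exact
    df
  })
  do.call(rbind, out)
}

#' Read a Likert count table from CSV
#'
#' Expects the columns of [likert_table()]'s `items` argument plus the
#' number of respondents inferred from the row sums (which must be
#' constant).
#'
#' @param path CSV path.
#' @return A `likert_table`.
#' @export
read_likert_csv <- function(path) {
  if (!file.exists(path)) stop_parse("questionnaire file not found: ", path)
  items <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  sums <- unique(rowSums(as.matrix(items[, paste0("n", 1:7)])))
  if (length(sums) != 1L) {
    stop_validation("rows disagree on the respondent total: ",
                    paste(sums, collapse = ", "))
  }
  likert_table(items, sums)
}

#' @export
print.likert_table <- function(x, ...) {
  cat("<likert_table> ", nrow(x$items), " items, n = ", x$n_respondents,
      " respondents\n", sep = "")
  invisible(x)
}
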