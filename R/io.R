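#' @title Chart file input/output, reports and nomogram plots
#' @description
#' CSV readers and writers for chart-review records (UTF-8, header row,
#' ISO-8601 timestamps, decimal point regardless of locale), JSON/text audit
#' reports, and the nomogram figure showing the threshold curves with the
#' patient's TSB point.
#' @name cli_io
NULL

CHART_COLUMNS <- c("ga_weeks", "bw_g", "birth_datetime", "record_datetime",
                   "tsb_value", "tsb_unit", "risk_factors", "pt_given",
                   "exchange_given", "epoch")

#' Write treatment records to a chart CSV
#'
#' @param records list of [treatment_record()]s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_charts <- function(records, path) {
  df <- charts_data_frame(records)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

charts_data_frame <- function(records) {
  rows <- lapply(records, function(r) {
    p <- r$patient
    data.frame(
      ga_weeks = p$ga_weeks, bw_g = p$bw_g,
      birth_datetime = format(p$birth_datetime, "%Y-%m-%dT%H:%M:%S"),
      record_datetime = format(p$record_datetime, "%Y-%m-%dT%H:%M:%S"),
      tsb_value = p$tsb_value, tsb_unit = p$tsb_unit,
      risk_factors = paste(p$risk_factors, collapse = ";"),
      pt_given = r$pt_given, exchange_given = r$exchange_given,
      epoch = r$epoch, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read treatment records from a chart CSV
#'
#' Expects the documented header (`r paste(CHART_COLUMNS, collapse = ", ")`);
#' unknown columns are ignored with a warning. Malformed rows do not abort
#' parsing silently: every offending data row is collected and reported with
#' its line number in a single error.
#'
#' @param path CSV path.
#' @return List of [treatment_record()]s.
#' @export
read_charts <- function(path) {
  if (!file.exists(path)) stop_parse("chart file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  extra <- setdiff(names(df), CHART_COLUMNS)
  if (length(extra)) {
    warning("ignoring unknown chart column(s): ", paste(extra, collapse = ", "))
  }
  missing_cols <- setdiff(CHART_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop_parse("chart file missing column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  records <- vector("list", nrow(df))
  errors <- character()
  for (i in seq_len(nrow(df))) {
    rec <- tryCatch({
      tsb <- df$tsb_value[i]
      unit <- if (is.na(df$tsb_unit[i])) "mg_dl" else df$tsb_unit[i]
      patient <- patient_record(
        ga_weeks = df$ga_weeks[i], birth_datetime = df$birth_datetime[i],
        record_datetime = df$record_datetime[i], bw_g = df$bw_g[i],
        tsb_value = if (is.na(tsb)) NA_real_ else as.numeric(tsb),
        tsb_unit = unit,
        risk_factors = strsplit(df$risk_factors[i], ";", fixed = TRUE)[[1]])
      treatment_record(patient, pt_given = as.logical(df$pt_given[i]),
                       exchange_given = as.logical(df$exchange_given[i]),
                       epoch = df$epoch[i])
    }, error = function(e) {
      errors[[length(errors) + 1L]] <<-
        paste0("line ", i + 1L, ": ", conditionMessage(e))
      NULL
    })
    records[[i]] <- rec
  }
  if (length(errors)) {
    stop_parse("malformed chart row(s):\n  ", paste(errors, collapse = "\n  "))
  }
  records
}

#' Write an epoch-comparison report
#'
#' Emits a machine-readable JSON report mirroring the classification table's
#' layout (counts, display percentages, and the chi-square test for every
#' comparison) and, optionally, a per-record classification CSV.
#'
#' @param comparison an `epoch_comparison` from [compare_epochs()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(comparison, path) {
  stopifnot(inherits(comparison, "epoch_comparison"))
  n <- colSums(comparison$classification)
  payload <- list(
    n_evaluable = as.list(n),
    n_unevaluable = comparison$n_unevaluable,
    classification = lapply(
      stats::setNames(nm = rownames(comparison$classification)),
      function(row) {
        cnt <- comparison$classification[row, ]
        list(pre = unname(cnt[1]), post = unname(cnt[2]),
             pre_percent = round_half_up(100 * unname(cnt[1]) / unname(n[1])),
             post_percent = round_half_up(100 * unname(cnt[2]) / unname(n[2])),
             p_value = round(comparison$tests[[row]]$p_value, 3))
      }),
    tests = lapply(comparison$tests, function(t) {
      list(statistic = t$statistic, df = t$df,
           p_value = round(t$p_value, 3))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Plot a recommendation on its nomogram
#'
#' Draws the phototherapy and exchange-transfusion threshold curves for the
#' recommendation's stratum and risk class, with the infant's TSB marked at
#' its postnatal age.
#'
#' @param recommendation a `bilinorm_recommendation`.
#' @param guideline the `guideline_table` the recommendation was made with.
#' @param path optional file path; when given the figure is saved there.
#' @return The ggplot object, invisibly when saved.
#' @export
plot_nomogram <- function(recommendation, guideline = default_guideline(),
                          path = NULL) {
  stopifnot(inherits(recommendation, "bilinorm_recommendation"))
  rc <- recommendation$risk_class
  key <- recommendation$stratum$key
  curves <- lapply(
    stats::setNames(nm = INTERVENTIONS),
    function(iv) guideline_curve(guideline, key, iv, rc))
  grid <- seq(0, max(168, recommendation$age_hours), by = 1)
  df <- do.call(rbind, lapply(INTERVENTIONS, function(iv) {
    data.frame(intervention = iv, age_hours = grid,
               tsb = threshold_at(curves[[iv]], grid))
  }))
  pt <- data.frame(age_hours = recommendation$age_hours,
                   tsb = recommendation$tsb_mg_dl)
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$age_hours, y = .data$tsb,
                                        colour = .data$intervention)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(data = pt, ggplot2::aes(x = .data$age_hours,
                                                y = .data$tsb),
                        colour = "black", size = 3, inherit.aes = FALSE) +
    ggplot2::scale_colour_manual(
      values = c(phototherapy = "#1b9e77", exchange_transfusion = "#d95f02"),
      labels = c(phototherapy = "Phototherapy",
                 exchange_transfusion = "Exchange transfusion")) +
    ggplot2::labs(x = "Postnatal age (hours)",
                  y = "Total serum bilirubin (mg/dL)",
                  colour = NULL,
                  title = paste0("Nomogram: ", format(recommendation$stratum),
                                 ", ", rc),
                  subtitle = advice_label(recommendation$advice)) +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, g, width = 7, height = 5, dpi = 150)
    return(invisible(g))
  }
  g
}
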