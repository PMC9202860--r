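#' @title Treatment advice for an individual infant
#' @description
#' The decision engine places an infant's total serum bilirubin on the
#' stratum- and risk-appropriate nomogram and returns one of three advice
#' tiers: no treatment, start phototherapy, or immediately start intensive
#' phototherapy and consider exchange transfusion.
#' @name decision_engine
NULL

RISK_FACTORS <- c("abo_rh_incompatibility", "haemolysis", "other_illness",
                  "hypoalbuminemia", "none_declared", "unknown")
ADVICE_TIERS <- c("no_treatment", "start_phototherapy",
                  "intensive_pt_consider_exchange")

#' Hypoalbuminemia cut-off used in the risk-factor definitions
#'
#' Stored verbatim as printed in the source material: value 30, unit
#' `"mg/L"`. Note the conventional clinical unit for a serum albumin cut-off
#' is g/L (a 30 g/L cut-off is standard); the printed mg/L is very likely a
#' typo, but it is kept verbatim here rather than silently corrected, and it
#' is configurable by users who construct their own risk flags upstream.
#' The engine itself only consumes the boolean `hypoalbuminemia` flag.
#' @format A list with elements `value` and `unit`.
#' @export
hypoalbuminemia_cutoff <- list(value = 30, unit = "mg/L")

#' Construct a validated patient record
#'
#' @param ga_weeks gestational age in completed weeks (valid range 20-45).
#' @param birth_datetime,record_datetime `POSIXct` timestamps or ISO-8601
#'   strings; the record time must not precede birth. Timezone-naive inputs
#'   are interpreted in the session timezone and compared directly.
#' @param bw_g birth weight in grams (valid range 300-6000).
#' @param tsb_value measured total serum bilirubin, or `NA` if not measured.
#' @param tsb_unit `"mg_dl"` or `"umol_l"`.
#' @param risk_factors character vector drawn from
#'   `r paste0('"', RISK_FACTORS, '"', collapse = ", ")`. `"none_declared"`
#'   must appear alone (it asserts the absence of the named factors).
#' @return A `patient_record` object; `tsb_mg_dl` is pre-converted.
#' @export
patient_record <- function(ga_weeks, birth_datetime, record_datetime, bw_g,
                           tsb_value = NA_real_, tsb_unit = c("mg_dl", "umol_l"),
                           risk_factors = "unknown") {
  tsb_unit <- match.arg(tsb_unit)
  if (!is_scalar_number(ga_weeks) || ga_weeks < 20 || ga_weeks > 45) {
    stop_domain("ga_weeks must be a number in [20, 45], got ", format(ga_weeks))
  }
  if (!is_scalar_number(bw_g) || bw_g < 300 || bw_g > 6000) {
    stop_domain("bw_g must be a number in [300, 6000], got ", format(bw_g))
  }
  birth <- as_timestamp(birth_datetime, "birth_datetime")
  record <- as_timestamp(record_datetime, "record_datetime")
  if (record < birth) stop_domain("record_datetime precedes birth_datetime")
  risk_factors <- unique(as.character(risk_factors))
  if (length(risk_factors) == 0L) stop_domain("risk_factors must be non-empty")
  bad <- setdiff(risk_factors, RISK_FACTORS)
  if (length(bad)) stop_domain("unknown risk factor(s): ", paste(bad, collapse = ", "))
  named <- setdiff(RISK_FACTORS, c("none_declared", "unknown"))
  if ("none_declared" %in% risk_factors && any(named %in% risk_factors)) {
    stop_domain("'none_declared' is exclusive of named risk factors")
  }
  tsb_mg_dl <- if (is.na(tsb_value)) NA_real_ else to_mg_dl(tsb_value, tsb_unit)
  structure(
    list(ga_weeks = ga_weeks, birth_datetime = birth, record_datetime = record,
         bw_g = bw_g, tsb_value = tsb_value, tsb_unit = tsb_unit,
         tsb_mg_dl = tsb_mg_dl, risk_factors = risk_factors),
    class = "patient_record"
  )
}

as_timestamp <- function(x, what) {
  if (inherits(x, "POSIXct")) return(x)
  out <- tryCatch(
    as.POSIXct(x, tz = "", tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
                                          "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                          "%Y-%m-%d")),
    error = function(e) NA)
  if (length(out) != 1L || is.na(out)) {
    stop_parse(what, " is not a valid ISO-8601 timestamp: '", x, "'")
  }
  out
}

#' Postnatal age in hours
#'
#' @param birth,record timestamps (`POSIXct` or ISO-8601 strings).
#' @return Exact hour difference as a real number.
#' @examples
#' postnatal_age_hours("2019-03-01T00:00", "2019-03-03T00:00") # 48
#' @export
postnatal_age_hours <- function(birth, record) {
  birth <- as_timestamp(birth, "birth")
  record <- as_timestamp(record, "record")
  if (record < birth) stop_domain("record timestamp precedes birth timestamp")
  as.numeric(difftime(record, birth, units = "hours"))
}

#' Convert a bilirubin measurement to mg/dL
#'
#' mg/dL passes through unchanged; umol/L is divided by 17.1 (the standard
#' conversion factor from the molar mass of bilirubin).
#'
#' @param value non-negative measurement; vectorised.
#' @param unit `"mg_dl"` or `"umol_l"`.
#' @return Value(s) in mg/dL.
#' @examples
#' to_mg_dl(171, "umol_l") # 10
#' @export
to_mg_dl <- function(value, unit = c("mg_dl", "umol_l")) {
  unit <- match.arg(unit)
  if (any(!is.finite(value)) || any(value < 0)) {
    stop_domain("TSB value must be finite and non-negative")
  }
  if (unit == "mg_dl") value else value / 17.1
}

#' Risk class from a set of risk-factor flags
#'
#' `"none_declared"` alone means uncomplicated hyperbilirubinemia (no risk);
#' any named factor, or `"unknown"` (factors other than those listed, or not
#' assessable), classifies the infant as having risk factors.
#'
#' @param risk_factors non-empty character vector of risk-factor flags.
#' @return `"no_risk"` or `"with_risk"`.
#' @export
risk_class_of <- function(risk_factors) {
  risk_factors <- as.character(risk_factors)
  if (length(risk_factors) == 0L) stop_domain("risk_factors must be non-empty")
  bad <- setdiff(risk_factors, RISK_FACTORS)
  if (length(bad)) stop_domain("unknown risk factor(s): ", paste(bad, collapse = ", "))
  if (identical(sort(unique(risk_factors)), "none_declared")) "no_risk" else "with_risk"
}

#' Treatment recommendation for one infant
#'
#' Implements the core decision rule: determine the stratum from gestational
#' age and birth weight, the risk class from the risk flags, and the
#' postnatal age from the timestamps; then compare the TSB (mg/dL) against
#' the phototherapy (PT) and exchange-transfusion (ET) thresholds at that
#' age. TSB at or above the ET threshold advises immediate intensive PT with
#' exchange transfusion considered; at or above the PT threshold, starting
#' PT; below both, no treatment. A TSB exactly at a threshold triggers the
#' treatment (conservative boundary rule).
#'
#' @param patient a [patient_record()] with a measured TSB.
#' @param guideline a `guideline_table`; defaults to [default_guideline()].
#' @return A `bilinorm_recommendation` with the advice tier and every
#'   intermediate quantity (stratum, risk class, age, TSB and both
#'   thresholds in mg/dL) for display or nomogram plotting.
#' @export
recommend <- function(patient, guideline = default_guideline()) {
  stopifnot(inherits(patient, "patient_record"))
  if (is.na(patient$tsb_mg_dl)) {
    stop_domain("TSB has not been measured: the infant cannot be placed on the ",
                "nomogram. Measure total serum bilirubin and re-enter the record.")
  }
  stratum <- stratum_for(patient$ga_weeks, patient$bw_g)
  risk_class <- risk_class_of(patient$risk_factors)
  age <- postnatal_age_hours(patient$birth_datetime, patient$record_datetime)
  pt_thr <- threshold_at(
    guideline_curve(guideline, stratum, "phototherapy", risk_class), age)
  et_thr <- threshold_at(
    guideline_curve(guideline, stratum, "exchange_transfusion", risk_class), age)
  tsb <- patient$tsb_mg_dl
  advice <- if (tsb >= et_thr) "intensive_pt_consider_exchange"
    else if (tsb >= pt_thr) "start_phototherapy"
    else "no_treatment"
  structure(
    list(advice = advice, stratum = stratum, risk_class = risk_class,
         age_hours = age, tsb_mg_dl = tsb, pt_threshold = pt_thr,
         et_threshold = et_thr, guideline_name = guideline$name,
         guideline_version = guideline$version),
    class = "bilinorm_recommendation"
  )
}

advice_label <- function(advice) {
  switch(advice,
    no_treatment = "No treatment indicated; continue monitoring.",
    start_phototherapy = "Start phototherapy.",
    intensive_pt_consider_exchange =
      "Start immediately with intensive phototherapy and consider exchange transfusion.")
}

#' @export
print.bilinorm_recommendation <- function(x, ...) {
  cat("<recommendation>\n")
  cat("  stratum:     ", format(x$stratum), "\n", sep = "")
  cat("  risk class:  ", x$risk_class, "\n", sep = "")
  cat(sprintf("  age:          %.1f h\n", x$age_hours))
  cat(sprintf("  TSB:          %.1f mg/dL (PT threshold %.1f, ET threshold %.1f)\n",
              x$tsb_mg_dl, x$pt_threshold, x$et_threshold))
  cat("  advice:      ", advice_label(x$advice), "\n", sep = "")
  invisible(x)
}

#' Parent-education checklist for a recommendation
#'
#' Returns the configured checklist of points to discuss with the infant's
#' family (adapted from the NICE neonatal-jaundice communication guidance),
#' tagged with the advice tier: items common to all tiers first, then
#' tier-specific items. Available in English (`"en"`) and Indonesian
#' (`"id"`).
#'
#' @param recommendation a `bilinorm_recommendation`, or an advice-tier
#'   string.
#' @param lang `"en"` or `"id"`.
#' @return A data frame with columns `tier` and `item` (ordered).
#' @export
education_checklist <- function(recommendation, lang = c("en", "id")) {
  lang <- match.arg(lang)
  advice <- if (inherits(recommendation, "bilinorm_recommendation")) {
    recommendation$advice
  } else {
    match.arg(as.character(recommendation), ADVICE_TIERS)
  }
  path <- system.file("extdata", "education_checklist.yaml", package = "bilinorm")
  if (path == "") stop_parse("education checklist resource not found")
  cfg <- yaml::read_yaml(path)
  pick <- function(section, tier) {
    items <- vapply(cfg[[section]], function(it) it[[lang]], character(1))
    data.frame(tier = tier, item = items, stringsAsFactors = FALSE)
  }
  out <- rbind(pick("common", "common"), pick(advice, advice))
  if (nrow(out) == 0L) stop_parse("education checklist resource is empty")
  out
}
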