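#' @title Stratified treatment-threshold nomograms
#' @description
#' A guideline table holds, for each patient stratum, the phototherapy (PT)
#' and exchange-transfusion (ET) threshold curves as total serum bilirubin
#' (TSB, mg/dL) versus postnatal age in hours, separately for infants with
#' and without risk factors. Strata follow the convention of the Indonesian
#' national practice: one nomogram for infants of gestational age >= 35
#' weeks, and four birth-weight bands for preterm infants (<= 1000,
#' 1001-1499, 1500-1999, > 1999 g), because exact gestational age is often
#' hard to establish.
#' @name guideline_tables
NULL

INTERVENTIONS <- c("phototherapy", "exchange_transfusion")
RISK_CLASSES <- c("no_risk", "with_risk")
STRATUM_KEYS <- c("term_near_term", "le_1000", "1001_1499", "1500_1999", "gt_1999")
BW_BANDS <- c("le_1000", "1001_1499", "1500_1999", "gt_1999")

#' Construct a threshold curve
#'
#' A piecewise-linear threshold of TSB (mg/dL) against postnatal age (hours).
#' Outside the knot range the curve is clamped to its terminal values (no
#' extrapolation), a deliberately conservative and deterministic choice.
#'
#' @param intervention `"phototherapy"` or `"exchange_transfusion"`.
#' @param risk_class `"no_risk"` or `"with_risk"`.
#' @param age_hours strictly increasing non-negative knot ages (hours).
#' @param tsb_mg_dl positive TSB values at the knots (mg/dL), same length.
#' @return An object of class `threshold_curve`.
#' @export
threshold_curve <- function(intervention, risk_class, age_hours, tsb_mg_dl) {
  intervention <- match.arg(intervention, INTERVENTIONS)
  risk_class <- match.arg(risk_class, RISK_CLASSES)
  if (!is.numeric(age_hours) || !is.numeric(tsb_mg_dl)) {
    stop_parse("threshold curve knots must be numeric")
  }
  if (length(age_hours) != length(tsb_mg_dl)) {
    stop_parse("age_hours and tsb_mg_dl must have equal length")
  }
  if (length(age_hours) < 2L) {
    stop_validation("a threshold curve needs at least 2 knots")
  }
  if (any(age_hours < 0)) {
    stop_validation("knot ages must be non-negative")
  }
  if (any(diff(age_hours) <= 0)) {
    stop_parse("knot ages must be strictly increasing")
  }
  if (any(tsb_mg_dl <= 0)) {
    stop_validation("all threshold TSB values must be positive")
  }
  structure(
    list(
      intervention = intervention,
      risk_class = risk_class,
      age_hours = as.numeric(age_hours),
      tsb_mg_dl = as.numeric(tsb_mg_dl)
    ),
    class = "threshold_curve"
  )
}

#' Query a threshold curve at a postnatal age
#'
#' Linear interpolation between knots; ages before the first or after the
#' last knot return the terminal knot value (clamp).
#'
#' @param curve a [threshold_curve()].
#' @param age_hours non-negative postnatal age(s) in hours; vectorised.
#' @return TSB threshold(s) in mg/dL.
#' @examples
#' cv <- threshold_curve("phototherapy", "no_risk", c(10, 20), c(8, 10))
#' threshold_at(cv, 15) # 9
#' @export
threshold_at <- function(curve, age_hours) {
  stopifnot(inherits(curve, "threshold_curve"))
  if (!is.numeric(age_hours) || any(!is.finite(age_hours)) || any(age_hours < 0)) {
    stop_domain("age_hours must be finite and non-negative")
  }
  stats::approx(curve$age_hours, curve$tsb_mg_dl, xout = age_hours,
                method = "linear", rule = 2)$y
}

#' Assign an infant to a nomogram stratum
#'
#' Gestational age >= 35 weeks selects the term/near-term nomogram regardless
#' of birth weight; below 35 weeks the birth-weight band decides, with band
#' edges <=1000, 1001-1499, 1500-1999, >1999 g interpreted on integer grams.
#' The 35.0-week boundary itself is assigned to the term nomogram.
#'
#' @param ga_weeks gestational age in completed weeks, in \[20, 45\].
#' @param bw_g birth weight in grams, in \[300, 6000\].
#' @return A `stratum` object with fields `kind` (`"term_near_term"` or
#'   `"preterm_bw"`), `bw_band` (band label or `NA`), and `key` (one of the
#'   five stratum keys used by the guideline table).
#' @examples
#' stratum_for(33, 2100)$key # "gt_1999"
#' stratum_for(38, 3200)$key # "term_near_term"
#' @export
stratum_for <- function(ga_weeks, bw_g) {
  if (!is_scalar_number(ga_weeks) || ga_weeks < 20 || ga_weeks > 45) {
    stop_domain("ga_weeks must be a number in [20, 45], got ", format(ga_weeks))
  }
  if (!is_scalar_number(bw_g) || bw_g < 300 || bw_g > 6000) {
    stop_domain("bw_g must be a number in [300, 6000], got ", format(bw_g))
  }
  if (ga_weeks >= 35) {
    st <- list(kind = "term_near_term", bw_band = NA_character_,
               key = "term_near_term")
  } else {
    band <- if (bw_g <= 1000) "le_1000"
      else if (bw_g <= 1499) "1001_1499"
      else if (bw_g <= 1999) "1500_1999"
      else "gt_1999"
    st <- list(kind = "preterm_bw", bw_band = band, key = band)
  }
  structure(st, class = "stratum")
}

#' @export
format.stratum <- function(x, ...) {
  if (x$kind == "term_near_term") "term/near-term (GA >= 35 wk)"
  else paste0("preterm, birth weight band ", x$bw_band, " g")
}

#' @export
print.stratum <- function(x, ...) {
  cat("<stratum>", format(x), "\n")
  invisible(x)
}

#' Load and validate a guideline threshold table
#'
#' Reads a YAML threshold-table file. The file must carry `name`, `version`,
#' `unit: mg_dl` and a `strata` map with all five strata
#' (`term_near_term`, `le_1000`, `1001_1499`, `1500_1999`, `gt_1999`), each
#' holding `phototherapy` and `exchange_transfusion` entries with `no_risk`
#' and `with_risk` curves given as parallel `age_hours` / `tsb_mg_dl` lists.
#'
#' All invariants are checked eagerly: knots strictly increasing, TSB > 0,
#' and on a dense age grid the ET curve never falls below the PT curve within
#' a (stratum, risk class), while the with-risk threshold never exceeds the
#' no-risk threshold for the same intervention.
#'
#' @param path path to the YAML file.
#' @return A `guideline_table` object.
#' @seealso [default_guideline()] for the packaged placeholder table.
#' @export
load_guideline <- function(path) {
  if (!file.exists(path)) stop_parse("guideline file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_parse("cannot parse guideline YAML: ",
                                                 conditionMessage(e)))
  guideline_table_from_list(raw, source = path)
}

guideline_table_from_list <- function(raw, source = "<list>") {
  for (field in c("name", "version", "unit", "strata")) {
    if (is.null(raw[[field]])) stop_parse("guideline missing field '", field, "'")
  }
  if (!identical(raw$unit, "mg_dl")) {
    stop_parse("guideline field 'unit' must be 'mg_dl', got '", raw$unit, "'")
  }
  missing_strata <- setdiff(STRATUM_KEYS, names(raw$strata))
  if (length(missing_strata)) {
    stop_parse("guideline missing strata: ", paste(missing_strata, collapse = ", "))
  }
  strata <- list()
  for (sk in STRATUM_KEYS) {
    entry <- raw$strata[[sk]]
    strata[[sk]] <- list()
    for (iv in INTERVENTIONS) {
      if (is.null(entry[[iv]])) {
        stop_parse("stratum '", sk, "' missing intervention '", iv, "'")
      }
      for (rc in RISK_CLASSES) {
        spec <- entry[[iv]][[rc]]
        if (is.null(spec) || is.null(spec$age_hours) || is.null(spec$tsb_mg_dl)) {
          stop_parse("stratum '", sk, "', intervention '", iv,
                     "' missing '", rc, "' curve (age_hours/tsb_mg_dl)")
        }
        strata[[sk]][[iv]][[rc]] <- threshold_curve(
          iv, rc, unlist(spec$age_hours), unlist(spec$tsb_mg_dl))
      }
    }
  }
  gt <- structure(
    list(name = raw$name, version = as.character(raw$version),
         unit = "mg_dl", strata = strata, source = source),
    class = "guideline_table"
  )
  validate_guideline(gt)
  gt
}

#' Validate cross-curve ordering invariants of a guideline table
#'
#' Checks, on a dense hourly grid spanning each stratum's knots, that the
#' exchange-transfusion threshold is never below the phototherapy threshold
#' within a risk class, and that with-risk thresholds never exceed no-risk
#' thresholds for the same intervention. Violations raise a validation error
#' naming the stratum and the first offending age.
#'
#' @param guideline a `guideline_table`.
#' @return The table, invisibly, if valid.
#' @export
validate_guideline <- function(guideline) {
  stopifnot(inherits(guideline, "guideline_table"))
  for (sk in STRATUM_KEYS) {
    curves <- guideline$strata[[sk]]
    ages <- sort(unique(c(
      unlist(lapply(curves, function(iv) lapply(iv, function(cv) cv$age_hours))),
      seq(0, 168, by = 0.5))))
    for (rc in RISK_CLASSES) {
      pt <- threshold_at(curves$phototherapy[[rc]], ages)
      et <- threshold_at(curves$exchange_transfusion[[rc]], ages)
      bad <- which(et < pt - 1e-9)
      if (length(bad)) {
        stop_validation("stratum '", sk, "' (", rc, "): exchange threshold below ",
                        "phototherapy threshold at age ", ages[bad[1]], " h")
      }
    }
    for (iv in INTERVENTIONS) {
      nr <- threshold_at(curves[[iv]]$no_risk, ages)
      wr <- threshold_at(curves[[iv]]$with_risk, ages)
      bad <- which(wr > nr + 1e-9)
      if (length(bad)) {
        stop_validation("stratum '", sk, "' (", iv, "): with-risk threshold above ",
                        "no-risk threshold at age ", ages[bad[1]], " h")
      }
    }
  }
  invisible(guideline)
}

#' Retrieve one curve from a guideline table
#'
#' @param guideline a `guideline_table`.
#' @param stratum a `stratum` object or a stratum key string.
#' @param intervention `"phototherapy"` or `"exchange_transfusion"`.
#' @param risk_class `"no_risk"` or `"with_risk"`.
#' @return The requested [threshold_curve()].
#' @export
guideline_curve <- function(guideline, stratum, intervention, risk_class) {
  stopifnot(inherits(guideline, "guideline_table"))
  key <- if (inherits(stratum, "stratum")) stratum$key else as.character(stratum)
  if (!key %in% STRATUM_KEYS) stop_domain("unknown stratum key '", key, "'")
  intervention <- match.arg(intervention, INTERVENTIONS)
  risk_class <- match.arg(risk_class, RISK_CLASSES)
  guideline$strata[[key]][[intervention]][[risk_class]]
}

#' The packaged default guideline table
#'
#' Loads the threshold table shipped with the package. These curves are a
#' synthetic placeholder: the numeric thresholds of the national guideline
#' the tool operationalises are not public in a citable form, so the package
#' ships a table with the same structure (term curve shaped like the
#' AAP-2004-style nomogram that such guidelines adapt; age-ramped preterm
#' band curves, lower for lower birth weight and for risk factors). Replace
#' it with [load_guideline()] on a site-specific file for clinical use.
#'
#' @return A `guideline_table`.
#' @export
default_guideline <- function() {
  path <- system.file("extdata", "guideline_default.yaml", package = "bilinorm")
  if (path == "") stop_parse("packaged default guideline not found")
  load_guideline(path)
}

#' @export
print.guideline_table <- function(x, ...) {
  cat("<guideline_table>", x$name, " (version ", x$version, ")\n", sep = "")
  cat("  unit: mg/dL; strata: ", paste(names(x$strata), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
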