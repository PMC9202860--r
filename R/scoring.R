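#' @title Acute and chronic bilirubin-neurotoxicity scoring
#' @description
#' Two clinical scores accompany the treatment advice. The modified
#' bilirubin-induced neurological dysfunction score (BIND-M) grades acute
#' bilirubin encephalopathy (ABE) from four examination items: mental
#' status, muscle tone, altered cry and altered gaze. The kernicterus
#' spectrum disorder (KSD) score grades the risk of chronic sequelae from
#' seven components (highest TSB, risk factors, neurological examination at
#' presentation and at follow-up, enamel dysplasia, auditory brainstem
#' response, MRI findings). The category bands are fixed; the per-item point
#' rubrics are configurable because different sites adapt them.
#' @name neuro_scoring
NULL

BIND_M_DEFAULT_MAXIMA <- c(mental_status = 3L, muscle_tone = 3L,
                           altered_cry = 2L, altered_gaze = 1L)
KSD_COMPONENTS <- c("highest_tsb", "risk_factors", "neuro_exam_presentation",
                    "neuro_exam_followup", "enamel_dysplasia", "abr", "mri")
KSD_DEFAULT_MAXIMA <- c(highest_tsb = 3L, risk_factors = 1L,
                        neuro_exam_presentation = 3L, neuro_exam_followup = 3L,
                        enamel_dysplasia = 1L, abr = 1L, mri = 2L)

#' BIND-M assessment and acute bilirubin encephalopathy band
#'
#' Sums the four examination items and classifies the total:
#' 0 = no ABE; 1-4 = mild ABE; 5-6 = moderate ABE; above 6 = severe ABE.
#'
#' @param mental_status,muscle_tone,altered_cry,altered_gaze non-negative
#'   integer item scores, each at most its configured maximum.
#' @param maxima named integer vector of per-item maxima. The default
#'   (3, 3, 2, 1) is a documented package convention; sites using a
#'   different rubric pass their own maxima.
#' @return A `bind_m_result` with `items`, `total` and `band` (one of
#'   `"no_abe"`, `"mild_abe"`, `"moderate_abe"`, `"severe_abe"`).
#' @examples
#' bind_m_classify(muscle_tone = 1, altered_cry = 1)$band # "mild_abe"
#' @export
bind_m_classify <- function(mental_status = 0L, muscle_tone = 0L,
                            altered_cry = 0L, altered_gaze = 0L,
                            maxima = BIND_M_DEFAULT_MAXIMA) {
  items <- c(mental_status = mental_status, muscle_tone = muscle_tone,
             altered_cry = altered_cry, altered_gaze = altered_gaze)
  check_item_scores(items, maxima, "BIND-M")
  total <- sum(items)
  band <- bind_m_band(total)
  structure(list(items = items, total = total, band = band),
            class = "bind_m_result")
}

#' BIND-M band from a total score
#' @param total non-negative integer total score.
#' @return Band label.
#' @export
bind_m_band <- function(total) {
  if (!is_scalar_number(total) || total < 0 || total != round(total)) {
    stop_domain("BIND-M total must be a non-negative integer")
  }
  if (total == 0) "no_abe"
  else if (total <= 4) "mild_abe"
  else if (total <= 6) "moderate_abe"
  else "severe_abe"
}

#' KSD assessment and kernicterus band
#'
#' Sums the seven component scores (total capped at 14 by the component
#' maxima) and classifies: 0-2 no kernicterus, 3-5 possible, 6-9 probable,
#' 10-14 definite kernicterus.
#'
#' @param components named non-negative integer vector over
#'   `r paste0('"', KSD_COMPONENTS, '"', collapse = ", ")`; omitted
#'   components default to 0.
#' @param maxima named integer per-component maxima summing to 14 (default
#'   rubric: 3, 1, 3, 3, 1, 1, 2).
#' @return A `ksd_result` with `components`, `total` and `band`.
#' @examples
#' ksd_classify(c(highest_tsb = 3, neuro_exam_presentation = 2,
#'                neuro_exam_followup = 2))$band # "probable"
#' @export
ksd_classify <- function(components, maxima = KSD_DEFAULT_MAXIMA) {
  full <- stats::setNames(integer(length(KSD_COMPONENTS)), KSD_COMPONENTS)
  if (!is.null(components)) {
    components <- unlist(components)
    bad <- setdiff(names(components), KSD_COMPONENTS)
    if (length(bad)) stop_domain("unknown KSD component(s): ",
                                 paste(bad, collapse = ", "))
    full[names(components)] <- components
  }
  if (sum(maxima) != 14) stop_domain("KSD component maxima must sum to 14")
  check_item_scores(full, maxima, "KSD")
  storage.mode(full) <- "integer"
  total <- sum(full)
  if (total > 14) stop_domain("KSD total exceeds 14")
  structure(list(components = full, total = total, band = ksd_band(total)),
            class = "ksd_result")
}

#' KSD band from a total score
#' @param total integer total in \[0, 14\].
#' @return `"no_kernicterus"`, `"possible"`, `"probable"` or `"definite"`.
#' @export
ksd_band <- function(total) {
  if (!is_scalar_number(total) || total < 0 || total > 14 ||
      total != round(total)) {
    stop_domain("KSD total must be an integer in [0, 14]")
  }
  if (total <= 2) "no_kernicterus"
  else if (total <= 5) "possible"
  else if (total <= 9) "probable"
  else "definite"
}

check_item_scores <- function(items, maxima, label) {
  if (any(items < 0) || any(items != round(items))) {
    stop_domain(label, " item scores must be non-negative integers")
  }
  maxima <- maxima[names(items)]
  over <- names(items)[items > maxima]
  if (length(over)) {
    stop_domain(label, " item(s) above configured maximum: ",
                paste(over, collapse = ", "))
  }
  invisible(items)
}

#' @export
print.bind_m_result <- function(x, ...) {
  cat("<BIND-M> total ", x$total, " -> ", x$band, "\n", sep = "")
  invisible(x)
}

#' @export
print.ksd_result <- function(x, ...) {
  cat("<KSD> total ", x$total, " -> ", x$band, "\n", sep = "")
  invisible(x)
}
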