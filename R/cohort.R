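#' @title Seeded synthetic chart-review cohorts
#' @description
#' Generates two-epoch chart-review cohorts for testing the audit pipeline
#' without patient data. The generator is classification-first: for each
#' record it draws the intended adherence category (correct, over-, under-,
#' inappropriate treatment) from the configured per-epoch rates and then
#' constructs a TSB and treatment flags that are guaranteed to audit to that
#' category under the supplied guideline (e.g. over-treatment places the TSB
#' strictly below the phototherapy threshold by a positive noise margin and
#' sets phototherapy to given). No bilirubin kinetics are simulated: the
#' cohort emulates the audit-relevant structure of a chart review, not
#' physiology.
#' @name synthetic_cohort
NULL

#' Configuration for a synthetic two-epoch cohort
#'
#' Defaults are calibrated to the published chart-review epoch comparison:
#' 255 pre-introduction and 181 post-introduction records; a 226/436
#' probability of gestational age below 35 weeks; birth-weight display-band
#' probabilities (3, 42, 248, 143)/436 for <1000 / 1000-1499 / 1500-2499 /
#' >=2500 g; risk-category probabilities (3, 1, 250, 139, 43)/436 for
#' ABO-Rh / haemolysis / sick infant / none declared / unknown; and
#' per-epoch classification rates (97, 87, 35, 36)/255 pre and
#' (93, 57, 18, 13)/181 post for correct / over / under / inappropriate.
#' Postnatal age is drawn as a normal in days (mean 4.1, SD 2.7, the
#' cohort's summary statistics) truncated to \[0.25, 14\] days.
#'
#' @param n_pre,n_post records per epoch.
#' @param ga_lt35_prob probability of gestational age < 35 weeks.
#' @param bw_band_probs length-4 probability vector over the birth-weight
#'   display bands.
#' @param risk_category_probs length-5 probability vector over the risk
#'   categories.
#' @param target_rates 4 x 2 matrix (rows correct/over/under/inappropriate,
#'   columns pre/post) of intended classification rates; each column must
#'   sum to 1.
#' @param tsb_noise_sd SD (mg/dL) of the noise margin separating the
#'   constructed TSB from the threshold.
#' @param seed integer RNG seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_pre = 255L, n_post = 181L,
                          ga_lt35_prob = 226 / 436,
                          bw_band_probs = c(3, 42, 248, 143) / 436,
                          risk_category_probs = c(3, 1, 250, 139, 43) / 436,
                          target_rates = cbind(pre = c(97, 87, 35, 36) / 255,
                                               post = c(93, 57, 18, 13) / 181),
                          tsb_noise_sd = 1, seed = 1L) {
  stopifnot(n_pre >= 1, n_post >= 1, tsb_noise_sd > 0)
  check_simplex <- function(p, len, what) {
    if (length(p) != len || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop_domain(what, " must be ", len, " non-negative probabilities summing to 1")
    }
  }
  check_simplex(bw_band_probs, 4L, "bw_band_probs")
  check_simplex(risk_category_probs, 5L, "risk_category_probs")
  target_rates <- as.matrix(target_rates)
  if (!all(dim(target_rates) == c(4L, 2L)) || any(target_rates < 0) ||
      any(abs(colSums(target_rates) - 1) > 1e-9)) {
    stop_domain("target_rates must be a 4 x 2 matrix with columns summing to 1")
  }
  rownames(target_rates) <- CLASSIFICATIONS
  colnames(target_rates) <- EPOCHS
  if (!is_scalar_number(ga_lt35_prob) || ga_lt35_prob < 0 || ga_lt35_prob > 1) {
    stop_domain("ga_lt35_prob must be a probability")
  }
  structure(
    list(n_pre = as.integer(n_pre), n_post = as.integer(n_post),
         ga_lt35_prob = ga_lt35_prob, bw_band_probs = bw_band_probs,
         risk_category_probs = risk_category_probs, target_rates = target_rates,
         tsb_noise_sd = tsb_noise_sd, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

RISK_CATEGORY_FLAGS <- list(
  abo_rh_incompatibility = "abo_rh_incompatibility",
  haemolysis = "haemolysis",
  other_illness = "other_illness",
  none_declared = "none_declared",
  unknown = "unknown"
)

#' Generate a synthetic two-epoch cohort
#'
#' Draws demographics per the configuration, then constructs each record so
#' that its audit classification under `guideline` equals the category drawn
#' from the configured per-epoch rates. Deterministic for a fixed seed.
#'
#' @param config a [cohort_config()].
#' @param guideline a `guideline_table`.
#' @return List of [treatment_record()]s (pre epoch first).
#' @export
generate_cohort <- function(config, guideline = default_guideline()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  birth <- as.POSIXct("2019-01-01 00:00:00", tz = "UTC")
  out <- vector("list", config$n_pre + config$n_post)
  idx <- 0L
  for (epoch in EPOCHS) {
    n <- if (epoch == "pre") config$n_pre else config$n_post
    for (i in seq_len(n)) {
      idx <- idx + 1L
      out[[idx]] <- generate_record(config, guideline, epoch, birth)
    }
  }
  out
}

generate_record <- function(config, guideline, epoch, birth) {
  ga <- if (stats::runif(1) < config$ga_lt35_prob) {
    stats::runif(1, 28, 34.9)
  } else {
    stats::runif(1, 35, 41)
  }
  ga <- round(ga, 1)
  band <- sample.int(4L, 1L, prob = config$bw_band_probs)
  bw <- switch(band, stats::runif(1, 600, 999), stats::runif(1, 1000, 1499),
               stats::runif(1, 1500, 2499), stats::runif(1, 2500, 4000))
  bw <- round(bw)
  risk_cat <- sample.int(5L, 1L, prob = config$risk_category_probs)
  risk <- RISK_CATEGORY_FLAGS[[risk_cat]]
  age_days <- Inf
  while (age_days < 0.25 || age_days > 14) {
    age_days <- stats::rnorm(1, 4.1, 2.7)
  }
  age_h <- age_days * 24
  record_time <- birth + age_h * 3600
  target <- CLASSIFICATIONS[sample.int(4L, 1L,
                                       prob = config$target_rates[, epoch])]
  stratum <- stratum_for(ga, bw)
  rc <- risk_class_of(risk)
  pt_thr <- threshold_at(guideline_curve(guideline, stratum, "phototherapy", rc),
                         age_h)
  et_thr <- threshold_at(
    guideline_curve(guideline, stratum, "exchange_transfusion", rc), age_h)
  margin <- abs(stats::rnorm(1, 1.5, config$tsb_noise_sd)) + 0.1
  below <- function() {
    if (pt_thr <= 0.05) {
      stop_domain("cannot construct a TSB strictly below a threshold of ",
                  pt_thr, " mg/dL")
    }
    max(0.05, pt_thr - margin)
  }
  state <- switch(target,
    correct = if (stats::runif(1) < 0.5) {
      list(tsb = pt_thr + margin, pt = TRUE)
    } else {
      list(tsb = below(), pt = FALSE)
    },
    over_treatment = list(tsb = below(), pt = TRUE),
    under_treatment = list(tsb = pt_thr + margin, pt = FALSE),
    inappropriate = list(tsb = NA_real_, pt = TRUE)
  )
  tsb <- if (is.na(state$tsb)) NA_real_ else round(state$tsb, 2)
  patient <- patient_record(
    ga_weeks = ga, birth_datetime = birth, record_datetime = record_time,
    bw_g = bw, tsb_value = tsb, tsb_unit = "mg_dl", risk_factors = risk)
  treatment_record(
    patient, pt_given = state$pt,
    exchange_given = !is.na(tsb) && state$pt && tsb >= et_thr,
    epoch = epoch)
}
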