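test_that("postnatal age is the exact hour difference", {
  expect_equal(postnatal_age_hours("2019-03-01T00:00", "2019-03-03T00:00"), 48)
  expect_equal(postnatal_age_hours("2019-03-01T06:30", "2019-03-01T06:30"), 0)
  expect_equal(postnatal_age_hours("2019-03-01T00:00", "2019-03-01T01:30"), 1.5)
  expect_error(postnatal_age_hours("2019-03-02T00:00", "2019-03-01T00:00"),
               class = "bilinorm_domain_error")
})

test_that("unit conversion divides umol/L by 17.1 and round-trips", {
  expect_equal(to_mg_dl(17.2, "mg_dl"), 17.2)
  expect_equal(to_mg_dl(171, "umol_l"), 10)
  expect_equal(to_mg_dl(0, "umol_l"), 0)
  set.seed(7)
  v <- runif(50, 0, 500)
  expect_equal(to_mg_dl(v, "umol_l") * 17.1, v)  # round-trip oracle
  expect_error(to_mg_dl(-1, "mg_dl"), class = "bilinorm_domain_error")
})

test_that("risk class: only an explicit 'none declared' counts as no risk", {
  expect_identical(risk_class_of("abo_rh_incompatibility"), "with_risk")
  expect_identical(risk_class_of("none_declared"), "no_risk")
  expect_identical(risk_class_of("unknown"), "with_risk")
  expect_identical(risk_class_of(c("haemolysis", "other_illness")), "with_risk")
  expect_error(risk_class_of(character(0)), class = "bilinorm_domain_error")
})

test_that("the preterm ABO-incompatibility example routes to intensive treatment", {
  p <- make_patient(ga = 33, bw = 2100, tsb = 17.2, age_h = 48,
                    risk = "abo_rh_incompatibility")
  r <- recommend(p, default_guideline())
  expect_identical(r$stratum$key, "gt_1999")
  expect_identical(r$risk_class, "with_risk")
  expect_identical(r$advice, "intensive_pt_consider_exchange")
  expect_true(r$tsb_mg_dl >= r$et_threshold)
})

test_that("advice boundaries: zero TSB is untreated, threshold equality triggers", {
  g <- default_guideline()
  expect_identical(recommend(make_patient(tsb = 0), g)$advice, "no_treatment")
  # TSB exactly at the PT threshold starts phototherapy (>= rule); the
  # expected tier comes from a direct three-way enumeration of the rule.
  for (case in list(list(ga = 38, bw = 3000, age = 48, risk = "none_declared"),
                    list(ga = 31, bw = 1200, age = 30, risk = "unknown"))) {
    st <- stratum_for(case$ga, case$bw)
    rc <- risk_class_of(case$risk)
    pt_thr <- threshold_at(guideline_curve(g, st, "phototherapy", rc), case$age)
    et_thr <- threshold_at(guideline_curve(g, st, "exchange_transfusion", rc),
                           case$age)
    r_at_pt <- recommend(make_patient(case$ga, case$bw, pt_thr, case$age,
                                      case$risk), g)
    expect_identical(r_at_pt$advice, "start_phototherapy")
    r_at_et <- recommend(make_patient(case$ga, case$bw, et_thr, case$age,
                                      case$risk), g)
    expect_identical(r_at_et$advice, "intensive_pt_consider_exchange")
  }
})

test_that("a missing TSB refuses nomogram placement with actionable wording", {
  p <- make_patient(tsb = NA_real_)
  expect_error(recommend(p), "Measure total serum bilirubin",
               class = "bilinorm_domain_error")
})

test_that("recommend matches an independent threshold lookup on random patients", {
  set.seed(11)
  g <- default_guideline()
  tiers <- c(no_treatment = 1L, start_phototherapy = 2L,
             intensive_pt_consider_exchange = 3L)
  for (i in 1:2000) {
    ga <- runif(1, 25, 42)
    bw <- round(runif(1, 500, 4500))
    age <- runif(1, 0, 240)
    tsb <- runif(1, 0, 30)
    risk <- sample(c("none_declared", "unknown", "abo_rh_incompatibility"), 1)
    r <- recommend(make_patient(ga, bw, tsb, age, risk), g)
    # independent re-evaluation: explicit curve lookup + three-way comparison
    st <- stratum_for(ga, bw)
    rc <- risk_class_of(risk)
    pt_cv <- guideline_curve(g, st, "phototherapy", rc)
    et_cv <- guideline_curve(g, st, "exchange_transfusion", rc)
    pt_thr <- piecewise_eval(pt_cv$age_hours, pt_cv$tsb_mg_dl, age)
    et_thr <- piecewise_eval(et_cv$age_hours, et_cv$tsb_mg_dl, age)
    expected <- if (tsb >= et_thr) 3L else if (tsb >= pt_thr) 2L else 1L
    expect_identical(tiers[[r$advice]], expected)
  }
})

test_that("advice tier is monotone in TSB and never lower with risk factors", {
  set.seed(13)
  g <- default_guideline()
  tiers <- c(no_treatment = 1L, start_phototherapy = 2L,
             intensive_pt_consider_exchange = 3L)
  for (i in 1:400) {
    ga <- runif(1, 25, 42); bw <- round(runif(1, 500, 4500))
    age <- runif(1, 0, 200)
    tsbs <- sort(runif(4, 0, 30))
    adv <- vapply(tsbs, function(t) {
      tiers[[recommend(make_patient(ga, bw, t, age, "none_declared"), g)$advice]]
    }, integer(1))
    expect_true(all(diff(adv) >= 0))
    t0 <- tsbs[2]
    a_no <- tiers[[recommend(make_patient(ga, bw, t0, age, "none_declared"),
                             g)$advice]]
    a_risk <- tiers[[recommend(make_patient(ga, bw, t0, age, "unknown"),
                               g)$advice]]
    expect_gte(a_risk, a_no)
  }
})

test_that("education checklist is non-empty, tier-tagged, deterministic and bilingual", {
  p <- make_patient(ga = 33, bw = 2100, tsb = 17.2, age_h = 48,
                    risk = "abo_rh_incompatibility")
  r <- recommend(p)
  cl <- education_checklist(r)
  expect_gt(nrow(cl), 0)
  expect_true(all(cl$tier %in% c("common", r$advice)))
  expect_identical(cl, education_checklist(r))
  # the no-treatment tier must still carry follow-up/monitoring advice
  cl0 <- education_checklist("no_treatment")
  expect_true(any(grepl("follow-up|re-checked|monitor", cl0$item,
                        ignore.case = TRUE)))
  cl_id <- education_checklist(r, lang = "id")
  expect_identical(nrow(cl_id), nrow(cl))
  expect_false(identical(cl_id$item, cl$item))
})
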