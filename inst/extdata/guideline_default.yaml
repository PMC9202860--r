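# SYNTHETIC placeholder threshold table.
# The numeric thresholds of the national guideline this tool operationalises
# are not publicly printed; these curves reproduce only its STRUCTURE
# (term/near-term nomogram shaped like the AAP-2004-style curves such
# guidelines adapt, plus four age-ramped preterm birth-weight bands, lower
# thresholds for lower birth weight and for risk factors). Swap in a
# site-specific file via load_guideline() before any clinical use.
name: bilinorm synthetic placeholder thresholds
version: "0.1.0-synthetic"
unit: mg_dl
strata:
  term_near_term:
    phototherapy:
      no_risk:
        age_hours: [0, 24, 48, 72, 96, 120]
        tsb_mg_dl: [8, 12, 15, 18, 20, 21]
      with_risk:
        age_hours: [0, 24, 48, 72, 96, 120]
        tsb_mg_dl: [6, 10, 13, 15, 17, 18]
    exchange_transfusion:
      no_risk:
        age_hours: [0, 24, 48, 72, 96, 120]
        tsb_mg_dl: [16, 19, 22, 24, 25, 25]
      with_risk:
        age_hours: [0, 24, 48, 72, 96, 120]
        tsb_mg_dl: [14, 17, 19, 21, 22, 22]
  gt_1999:
    phototherapy:
      no_risk:
        age_hours: [0, 24, 48, 72, 96, 120]
        tsb_mg_dl: [7, 9, 11, 13, 14, 14]
      with_risk:
        age_hours: [0, 24, 48, 72, 96, 120]
        tsb_mg_dl: [5, 7, 9, 11, 12, 12]
    exchange_transfusion:
      no_risk:
        age_hours: [0, 24, 48, 72, 96, 120]
        tsb_mg_dl: [13, 15, 17, 18, 19, 19]
      with_risk:
        age_hours: [0, 24, 48, 72, 96, 120]
        tsb_mg_dl: [11, 13, 15, 16, 17, 17]
  1500_1999:
    phototherapy:
      no_risk:
        age_hours: [0, 24, 48, 72, 96, 120]
        tsb_mg_dl: [6, 8, 10, 11, 12, 12]
      with_risk:
        age_hours: [0, 24, 48, 72, 96, 120]
        tsb_mg_dl: [4, 6, 8, 9, 10, 10]
    exchange_transfusion:
      no_risk:
        age_hours: [0, 24, 48, 72, 96, 120]
        tsb_mg_dl: [12, 13, 15, 16, 17, 17]
      with_risk:
        age_hours: [0, 24, 48, 72, 96, 120]
        tsb_mg_dl: [10, 11, 13, 14, 15, 15]
  1001_1499:
    phototherapy:
      no_risk:
        age_hours: [0, 24, 48, 72, 96, 120]
        tsb_mg_dl: [5, 6, 8, 9, 10, 10]
      with_risk:
        age_hours: [0, 24, 48, 72, 96, 120]
        tsb_mg_dl: [4, 5, 6, 7, 8, 8]
    exchange_transfusion:
      no_risk:
        age_hours: [0, 24, 48, 72, 96, 120]
        tsb_mg_dl: [10, 11, 13, 14, 15, 15]
      with_risk:
        age_hours: [0, 24, 48, 72, 96, 120]
        tsb_mg_dl: [8, 9, 11, 12, 13, 13]
  le_1000:
    phototherapy:
      no_risk:
        age_hours: [0, 24, 48, 72, 96, 120]
        tsb_mg_dl: [4, 5, 6, 7, 8, 8]
      with_risk:
        age_hours: [0, 24, 48, 72, 96, 120]
        tsb_mg_dl: [3, 4, 5, 5.5, 6, 6]
    exchange_transfusion:
      no_risk:
        age_hours: [0, 24, 48, 72, 96, 120]
        tsb_mg_dl: [8, 9, 10, 11, 12, 12]
      with_risk:
        age_hours: [0, 24, 48, 72, 96, 120]
        tsb_mg_dl: [6, 7, 8, 9, 10, 10]
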