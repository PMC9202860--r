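Package: bilinorm
Title: Neonatal Hyperbilirubinemia Decision Support and Guideline-Adherence Audit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Decision support for neonatal hyperbilirubinemia management:
    stratified phototherapy and exchange-transfusion threshold nomograms with
    continuous age lookup, treatment advice for individual infants, BIND-M
    acute bilirubin encephalopathy scoring and kernicterus spectrum disorder
    (KSD) risk scoring, a parent-education checklist, a chart-review audit
    engine that classifies administered treatment against the guideline
    (correct, over-, under-, inappropriate) and compares epochs with Pearson
    chi-square tests, seven-point Likert questionnaire summaries, and a seeded
    synthetic-cohort generator for end-to-end testing. Threshold tables are
    versioned configuration files; the shipped default is a documented
    synthetic placeholder.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
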