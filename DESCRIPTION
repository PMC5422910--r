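Package: phenoval
Title: Administrative-Data Phenotyping Algorithms and Diagnostic Accuracy Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Defines and validates computable phenotype algorithms over
    administrative health data coded in ICD-10, ICD-9 and CCI. Ships the
    code lists and three model variants used to identify endoscopic sinus
    surgery for chronic rhinosinusitis (ESS-CRS) in hospital encounter
    data, a hierarchical prefix/wildcard code matcher, full diagnostic
    accuracy machinery (2x2 tables, sensitivity, specificity, predictive
    values, likelihood ratios, exact and approximate confidence
    intervals), and a seeded synthetic cohort generator that can either
    reproduce a printed confusion structure exactly or simulate from free
    presence probabilities, including the all-predicted-cases plus
    random-controls internal validation sampling design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
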