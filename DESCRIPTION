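Package: vapscore
Title: Clinical Scores and Diagnostic Accuracy for Pediatric Ventilator-Associated Pneumonia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes the Clinical Pulmonary Infection Score (CPIS) and its
    lung-ultrasound and procalcitonin extensions (CPIS-LUS, CPIS-PCT,
    CPIS-PLUS, LUS) for suspected ventilator-associated pneumonia episodes
    in pediatric intensive care; derives point scores from cohort
    contingency tables via log-odds-ratio scaling; evaluates diagnostic
    accuracy (sensitivity, specificity, predictive values with Wilson
    intervals, Mann-Whitney AUC with DeLong variance and paired
    comparisons, Youden-optimal cut-offs); and simulates suspected-VAP
    cohorts with calibrated conditional feature distributions so the whole
    pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
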