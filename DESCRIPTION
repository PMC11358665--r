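Package: labelaudit
Title: Auditing Gold-Standard Label Errors in Diagnostic Classifier Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and correcting human (gold-standard) label
    errors when evaluating a binary screening classifier on large real-world
    data sets. Implements stratified adjudication sampling of
    classifier/label discrepancies, exact binomial estimation of stratum
    label-error rates, correction of the label distribution and of the
    confusion matrix, pre/post diagnostic metrics with uncertainty
    propagation, lab versus real-world gap analysis, and a seeded synthetic
    screening-cohort generator with a two-stage human grading workflow for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
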