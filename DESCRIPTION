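Package: hierva
Title: Standardized Hierarchical Cause-of-Death Assignment from Verbal Autopsy Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assigning causes of death to under-5 verbal autopsy
    (VA) records with a standardized, tiered expert algorithm, and for turning
    the assignments into survey-weighted cause-specific mortality fractions
    and rates. Case definitions are declarative boolean rules over symptom
    indicators, evaluated under a tier hierarchy that resolves competing
    diagnoses; comorbid pneumonia/diarrhea assignments are redistributed
    proportionally to the single-cause masses. Uncertainty ranges come from a
    stratified clustered bootstrap that resamples primary sampling units and
    reruns the full nonlinear pipeline, optionally propagating under-5
    mortality-rate uncertainty into cause-specific mortality rates; a
    two-sample bootstrap test compares fractions between survey waves. A
    synthetic DHS-style population generator with known cause structure makes
    every stage testable without access to restricted survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
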