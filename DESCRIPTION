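Package: dynamark
Title: Early Dynamic Biomarkers of Treatment Response from PET and ctDNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Patient-level evaluation of early treatment response in
    metastatic cancer from lesion-level FDG-PET measurements and
    variant-level circulating tumor DNA (ctDNA) calls. Implements the
    consistent ("dominance") four-class metabolic response classification
    at configurable SUVmax cut-offs, PERCIST target selection and
    response, scan-pair quality control, variant filtering and per-patient
    ctDNA detection, the circulating DNA ratio (CDR) and related dynamics
    statistics, combined PET/ctDNA grouping with negative-predictive-value
    summaries for rapid progression, Kaplan-Meier / log-rank / univariate
    Cox outcome analyses, Schoenfeld event-count design calculations, and
    a synthetic cohort generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
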