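Package: dentale
Title: DENTALE Radiographic Scoring of Late Dental Effects in Childhood
    Cancer Survivors
Version: 0.1.0
Authors@R:
    person("DENTALE", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the DENTALE weighted scoring system for late dental
    and maxillofacial adverse effects read from orthopantomograms (panoramic
    radiographs) of childhood-cancer survivors. Provides the permanent-
    dentition data model in FDI notation with sextant mapping, the weighted
    item scorer with the localized-pathology sextant adjustment and the
    referral decision rule, interobserver reliability via two-way
    intraclass correlation coefficients, diagnostic accuracy statistics
    (sensitivity, specificity, predictive values with Wilson intervals) and
    referral-threshold sweeps, a synthetic multi-rater cohort simulator for
    validating the statistics without radiographs, and JSON/CSV readers and
    writers with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
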