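Package: radiomir
Title: Radiosensitivity miRNA Signature Screening and Cohort Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for deriving a radiosensitivity microRNA signature from
    dual-channel miRNA microarray experiments and a three-arm patient cohort.
    Implements control-ratio normalization of triplicate probe fluorescence,
    radiation-response fold-change screening in ATM-proficient and
    ATM-deficient cell lines, perfect-separation threshold (theta-interval)
    analysis of fluorescence, hit calling by a two-standard-deviation rule,
    a cross-cohort directional-concordance screen against responder and
    progressor patient groups, an ATM protein (RPPA) group comparison, and a
    Fisher-z correlation-based sample-size formula. Ships synthetic
    generators for probe-level array experiments and patient cohorts with
    known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
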