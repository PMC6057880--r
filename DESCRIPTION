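Package: pdxtrial
Title: Response Scoring, Survival and Biomarker Analytics for
    Patient-Derived Xenograft Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for 1x1x1 patient-derived xenograft (PDX)
    pre-clinical trials. Converts caliper measurements to tumor volumes,
    scores treated-over-control (T/C) growth ratios and classifies models
    into progression, suppression and regression groups; derives
    doubling-time progression-free-survival records and compares response
    groups with Kaplan-Meier estimates and the log-rank (Mantel-Cox) test;
    disambiguates graft (human) from host (mouse) sequencing reads;
    provides a sensitive threshold-based pileup variant caller with
    call-set merging, an annotation-driven variant retention cascade,
    confidence flagging and oncoprint construction; and normalizes RNA-seq
    counts by median-of-ratios size factors, bins drug-efflux-pump
    (ABCB1-style) expression into resistance categories and runs a
    batch-stratified permutation test for differential expression. A
    synthetic-data generator with full ground truth emulates every input.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ggplot2,
    stats,
    survival,
    utils
Suggests:
    DESeq2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
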