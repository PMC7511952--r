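Package: methmarker
Title: Multi-Omics Screening and Evaluation of Methylation Markers of
    Response to Neoadjuvant Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery and evaluation of DNA-methylation predictive markers
    of pathological complete response (pCR) to neoadjuvant therapy in
    HER2-positive breast cancer. Implements tumor/normal somatic-variant
    filtering by six evidence rules, coverage-ratio copy-number calls,
    volcano screening of differential expression, an Infinium-450K-style
    beta-value marker screen (reference-unmethylated universe, per-CpG
    threshold-classifier metrics, consecutive-probe region aggregation),
    combined-marker contingency evaluation with age stratification, and
    paired baseline/on-treatment delta-beta response monitoring. A seeded
    synthetic-cohort generator with planted marker signal makes the full
    pipeline testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
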