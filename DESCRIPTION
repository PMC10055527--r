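Package: rplphewas
Title: Phenome-Wide Case-Control Association Analysis of Recurrent
    Pregnancy Loss from Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for case-control phenome-wide association studies
    (PheWAS) of recurrent pregnancy loss (RPL) built on OMOP-shaped
    electronic health record extracts.  Implements temporal cohort
    phenotyping with RPL qualifying rules (diagnosis code, history of
    loss followed by a loss, or two losses at least 90 days apart),
    Phecode aggregation of ICD9/ICD10 diagnoses, confounder-adjusted
    association testing with penalized-spline age adjustment,
    Benjamini-Hochberg multiple-testing correction, age-stratified and
    healthcare-utilization sensitivity analyses, cross-site validation
    with hypergeometric overlap enrichment, UMAP cohort visualization,
    small-count redaction, and a two-site synthetic EHR generator with
    planted odds ratios so the whole pipeline can be exercised and
    validated without access to protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    splines,
    mgcv,
    Matrix,
    data.table,
    jsonlite,
    ggplot2,
    uwot
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
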