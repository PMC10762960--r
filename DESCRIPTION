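Package: cobraMonitor
Title: In-Silico Fluorescent COBRA/Hi-SA Assay and ccfDNA Methylation
    Score Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for a fluorescent combined
    bisulfite restriction analysis (COBRA) liquid-biopsy panel targeting
    two promoter regions each of EFEMP1, SFRP2 and UNC5C. Provides an
    in-silico assay model (bisulfite conversion, HhaI site retention,
    restriction digestion, labeled-fragment electropherograms and
    methylation-ratio quantification), the composite scoring system
    (methylation score, recovery score and combination score Fc),
    cohort-level diagnostic evaluation (logistic fits, ROC/AUC with
    DeLong comparison, stratified cross-validation, Dunn and rank-sum
    tests), and longitudinal treatment-response monitoring (approximation
    curves, rise detection, lead time before progressive disease).
    Includes calibrated synthetic-cohort and trajectory generators so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports: methods, stats, utils, tools, S4Vectors, IRanges, Biostrings,
    pROC, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
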