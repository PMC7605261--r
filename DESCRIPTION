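Package: epidriver
Title: Pan-Cancer Multi-Omics Prioritization of Epigenetic Regulator Driver Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates somatic mutation, copy-number, expression and DNA
    methylation data for epigenetic regulator genes (ERGs) across cancer
    cohorts. Implements alteration-landscape summaries with the
    deep-amplification/deletion regrouping and category rules, a
    competition-ranking Pan-Cancer Driver score and a percentile-based
    Multi-Omics Driver score, co-occurrence/mutual-exclusivity odds-ratio
    meta-analysis with the Haldane-Anscombe correction, promoter eQTM
    scanning, hallmark Fisher enrichment, and pooled CRISPR knockout screen
    quantification with cross-method, cross-timepoint consensus hit-calling.
    A fully parameterized synthetic-cohort generator with planted signal
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
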