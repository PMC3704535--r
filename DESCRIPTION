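Package: pansubtype
Title: Cross-Tissue Commonality Analysis of Cancer Molecular Subtypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies molecular commonality between cancer subtypes across
    tissues from bulk expression cohorts. Builds per-sample transcriptional
    profiles (median-centered expression) and pathway profiles (single-sample
    GSEA enrichment scores), correlates them across cohorts with Spearman rank
    correlation, summarises subtype pairs by their median correlation, and
    derives a subtype phylogeny by average-linkage clustering of the
    1 - median-rho dissimilarity. Per-subtype one-vs-rest gene set enrichment
    analysis with a phenotype-permutation null yields NES and FDR q-values,
    from which pathway recurrence across tissues is tabulated. Pooled pathway
    profiles are clustered into two groups and per-subtype overrepresentation
    is tested by chi-squared. A synthetic multi-cohort generator with planted
    cross-tissue gene programs makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
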