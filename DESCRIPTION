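Package: mogsea
Title: Multi-Omics Pathway Enrichment by Combining Per-Layer Gene Set
    Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pathway enrichment analysis across transcriptome, proteome and
    metabolome layers. Each omics layer is analysed separately with a
    gene-set enrichment analysis based on the weighted Kolmogorov-Smirnov
    running-sum statistic, a feature-set permutation null, normalized
    enrichment scores and Benjamini-Hochberg adjustment. Per-layer pathway
    p-values are then aggregated into a single multi-omics p-value with
    Fisher's combined probability test, Stouffer's Z-transform (unweighted
    or weighted) or Edgington's additive method. Includes GMT pathway
    readers and writers, identifier translation from user-supplied lookup
    tables, a fully self-contained synthetic multi-omics study generator,
    and a command-line workflow.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    fgsea,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
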