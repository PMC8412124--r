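Package: regulonScan
Title: Transcription Factor Regulon Over-Representation Analysis with
    Cross-Species Transfer
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate transcriptional regulators from
    differential-expression output by testing ChIP-derived regulons
    (TF target gene sets) for over-representation among upregulated
    genes with an exact hypergeometric upper-tail test, calibrates the
    unstated expressed-gene universe size from published enrichment
    rows, transfers regulons across species through an ortholog map
    for re-enrichment, confirms targets by Spearman correlation with
    an exact permutation null for small samples, and intersects
    enriched pathways with regulons. Includes a seed-reproducible
    planted-regulon simulator so every stage is testable offline, and
    a pipeline driver that writes tabular outputs plus a reproducible
    run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: GeneRegulation, GeneSetEnrichment, Transcriptomics, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
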