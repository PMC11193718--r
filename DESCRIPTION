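Package: breakbalance
Title: MMEJ:NHEJ Pathway Balance and Chromatin Context-Dependency Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the balance between microhomology-mediated end-joining
    (MMEJ) and non-homologous end-joining (NHEJ) double-strand-break repair from
    multiplexed barcoded reporter screens, detects chromatin context-dependencies
    (CCDs) of DNA repair proteins by a three-step linear modeling approach with
    per-feature synergy scores, compares CCD patterns within and across cell
    types via cosine similarity against random-pair nulls and protein-protein
    interaction cliques, and tests chromatin-compartment-dependent shifts of
    repair-signature deletions in tumor cohorts using lamina-associated-domain
    stratification, bootstrap z-scores and Stouffer meta-analysis. A synthetic
    data module generates reporter screens and tumor cohorts with planted ground
    truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    igraph,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
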