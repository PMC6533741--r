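Package: cleftminer
Title: Candidate-Gene Catalogs, miRNA Target-Set Enrichment, and Trio TDT
    Scans for Orofacial Clefts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the genetic architecture of cleft lip with
    or without cleft palate (CL/P). Curates and validates candidate-gene
    catalogs, integrates miRNA-target interaction evidence from multiple
    prediction sources with an experimental-validation filter, tests each
    miRNA's target set for enrichment of candidate genes (one-sided
    Fisher's exact test with Benjamini-Hochberg false discovery rate
    control and seed-family aggregation), runs generic hypergeometric
    gene-set enrichment against user-supplied GMT annotation collections,
    and performs transmission disequilibrium tests on parent-offspring
    trios read from PLINK-style PED/MAP text, with SNP-to-gene interval
    assignment and tiered significance thresholds. Includes seeded
    synthetic-data generators (planted target-set enrichment, trio
    genotypes with configurable transmission distortion) so every analysis
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    fgsea,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
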