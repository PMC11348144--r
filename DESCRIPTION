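Package: dmrlink
Title: Differential Methylation Regions and Their Link to Gene Expression in
    Tumor Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls differentially methylated cytosines (DMCs) and regions
    (DMRs) in whole-genome bisulfite sequencing data by comparing individual
    tumor methylomes against an averaged normal-control profile, annotates
    them to genomic elements (promoters, gene bodies, exons, introns,
    enhancers, repeats), derives cross-tumor recurrence signatures, and
    integrates recurrent promoter methylation change with gene expression
    change. Includes a synthetic-data generator that plants DMRs and coupled
    expression changes with recorded ground truth, so every stage of the
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
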