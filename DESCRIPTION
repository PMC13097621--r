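Package: terewire
Title: Transposable-Element Insertion Context, Hybrid Splicing, and
    piRNA Strand-Bias Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring how transposable-element (TE) insertions
    rewire a host transcriptome in somatic cells. Classifies TE insertions
    by genomic context and orientation relative to host transcription,
    calls host-TE hybrid-splicing events from long-read transcript models,
    tests splicing competence against downstream-exon distance with a
    self-contained exact Mann-Whitney U test, quantifies strand-resolved
    piRNA production on TE consensus sequences, computes genome occupancy
    and cross-assembly enrichment, syntenic-coverage fractions and
    junction-spanning presence calls, scans insertion sites with
    position-weight matrices calibrated by exact dynamic programming, and
    builds accessibility metaprofiles with matched random controls. A
    seeded synthetic-data generator produces internally consistent toy
    datasets with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicAlignments,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
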