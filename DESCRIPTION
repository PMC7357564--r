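Package: ilpminer
Title: Mining and Characterization of Arthropod Insulin-Like Peptide Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A desk-scale pipeline for discovering insulin-like peptide (ilp)
    genes in arthropod sequence data and characterizing them. Implements
    iterative seed-based read recruitment with greedy overlap assembly,
    cysteine-framework precursor detection and family classification
    (insulin, aIGF, gonadulin, relaxin), half-spot expression quantification
    with splice-isoform partitioning, sequence-similarity neighbor-joining
    trees with bootstrap support, transmembrane-region extraction, and
    detection of the gonadulin-aIGF-relaxin synteny cluster. A synthetic-data
    module generates genomes, isoform transcripts and reads with complete
    planted truth so the whole analysis runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
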