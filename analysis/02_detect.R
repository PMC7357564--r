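#!/usr/bin/env Rscript
# Stage 2: detect insulin-framework precursors in the simulated genome, both
# from the annotated transcripts (recall) and from a raw six-frame ORF scan
# (specificity), and classify each into a family.

suppressPackageStartupMessages(library(ilpminer))

genome_tbl <- parse_sequences("results/genome.fasta", alphabet = "dna")
genome <- stats::setNames(genome_tbl$residues, genome_tbl$id)
features <- parse_features("results/genome_truth.gff3")

ann <- detect_in_annotation(genome, features)
flat <- ann[, c("mrna", "source", "family", "extension", "signal_end")]
flat$n_extra_cys <- vapply(ann$extra_cys, length, integer(1))
utils::write.table(flat, "results/precursors.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
write_sequences(tibble::tibble(id = ann$mrna, desc = ann$family,
                               residues = ann$protein, alphabet = "protein"),
                "results/precursors.fasta")

raw <- detect_precursors(genome, alphabet = "dna", min_aa = 60,
                         longest_only = TRUE)
cat("Annotated mRNAs with a framework precursor:", nrow(ann), "of",
    sum(features$type == "mRNA"), "\n")
cat("Family calls:", paste(sort(table(ann$family), decreasing = TRUE),
                           names(sort(table(ann$family), decreasing = TRUE)),
                           collapse = ", "), "\n")
cat("Raw ORF-scan hits on the genome:", nrow(raw),
    "(all should overlap planted genes)\n")
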