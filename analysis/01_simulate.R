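#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study system — a genome with two planted
# gonadulin-aIGF-relaxin clusters, the aIGF isoform transcripts, and an
# error-free read archive — and write everything (with ground truth) under
# results/.

suppressPackageStartupMessages(library(ilpminer))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
dir.create("results", showWarnings = FALSE)

syn <- make_genome(n_clusters = 2,
                   cluster_composition = c("gonadulin", "aIGF", "relaxin"),
                   intergenic = c(15000L, 30000L),
                   decoy_length = 200000L, seed = seed)
write_sequences(tibble::tibble(id = names(syn$genome), desc = "",
                               residues = unname(syn$genome),
                               alphabet = "dna"),
                "results/genome.fasta")
write_features(syn$features, "results/genome_truth.gff3")
write_sequences(tibble::tibble(id = names(syn$transcripts), desc = "",
                               residues = unname(syn$transcripts),
                               alphabet = "dna"),
                "results/transcripts.fasta")

# read archive: the first cluster's aIGF isoforms (3:2 isoform mixture, ~15%
# of the archive) over a background of unrelated transcripts
aigf <- grep("aIGF", names(syn$transcripts), value = TRUE)[1:2]
set.seed(seed + 2L)
bg <- stats::setNames(
  vapply(1:3, function(i) paste(sample(c("A", "C", "G", "T"), 1200,
                                       replace = TRUE), collapse = ""),
         character(1)),
  paste0("bg", 1:3))
sim <- simulate_reads(c(syn$transcripts[aigf], bg),
                      abundances = c(9, 6, 30, 30, 25),
                      n_spots = 1200, read_length = 90, seed = seed + 1L)
write_spots_fastq(sim$spots, "results/reads.fastq")
write_truth_tsv(sim$truth, "results/reads_truth.tsv")

cat("Planted", nrow(syn$gene_table), "genes on",
    length(syn$genome), "scaffolds;",
    nrow(sim$spots), "half spots simulated from", aigf[1], "and",
    aigf[2], "\n")
cat("Intergenic distances (cluster 1):",
    paste(syn$intergenic[[1]], collapse = ", "), "nt\n")
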