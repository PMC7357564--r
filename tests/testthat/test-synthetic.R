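test_that("generated precursors carry the planted framework and motifs", {
  for (fam in c("insulin", "gonadulin", "relaxin")) {
    g <- make_ilp_gene(ilp_gene_spec(fam), seed = 31)
    expect_length(g$transcripts, 1L)
    fw <- match_framework(g$proteins[[1]])
    expect_false(is.null(fw))
    expect_length(fw$positions, 6L)
    expect_equal(length(fw$extra_cys), 0L)
  }
  g <- make_ilp_gene(ilp_gene_spec("aIGF"), seed = 31)
  prot_long <- g$proteins[[1]]
  fw <- match_framework(prot_long)
  expect_gte(fw$extension, 40L)
  expect_false(is.null(detect_gtv_motif(prot_long)))
  argr <- detect_arginine_rich(prot_long)
  expect_false(is.null(argr))
  # the arginine-rich segment lies in the C-terminal extension
  expect_gt(argr[["start"]], fw$positions[6])
})

test_that("aIGF genes yield two isoforms differing only by the alt segment", {
  sp <- ilp_gene_spec("aIGF")
  g <- make_ilp_gene(sp, seed = 8)
  expect_length(g$transcripts, 2L)
  long <- g$transcripts[[1]]; short <- g$transcripts[[2]]
  exl <- sp$coding_exon_lengths
  p <- exl[1] + exl[2] + sp$alt_splice_offset     # last common base before alt
  alt_len <- exl[3] - sp$alt_splice_offset
  expect_equal(nchar(long) - nchar(short), alt_len)
  expect_equal(substring(long, 1, p), substring(short, 1, p))
  expect_equal(substring(long, p + alt_len + 1), substring(short, p + 1))
  # the included segment encodes the arginine-rich stretch with 2 cysteines
  alt_aa <- translate_cds(substring(long, p + 1, p + alt_len))
  expect_gte(sum(strsplit(alt_aa, "")[[1]] %in% c("R", "K")) / nchar(alt_aa), 0.5)
  expect_equal(sum(strsplit(alt_aa, "")[[1]] == "C"), 2L)
  # short isoform loses the arginine-rich segment but keeps the GTV motif
  expect_null(detect_arginine_rich(g$proteins[[2]]))
  expect_false(is.null(detect_gtv_motif(g$proteins[[2]])))
})

test_that("relaxin seven-cysteine variant is planted and tolerated", {
  g <- make_ilp_gene(ilp_gene_spec("relaxin", seven_cys = TRUE), seed = 3)
  expect_null(match_framework(g$proteins[[1]]))  # strict pattern rejects it
  fw <- match_framework(g$proteins[[1]],
                        framework_pattern(allow_extra_cysteines = TRUE))
  expect_length(fw$extra_cys, 1L)
  expect_error(ilp_gene_spec("insulin", seven_cys = TRUE), "relaxin")
})

test_that("gene generation is deterministic and validates exon framing", {
  sp <- ilp_gene_spec("aIGF")
  expect_identical(make_ilp_gene(sp, seed = 42), make_ilp_gene(sp, seed = 42))
  expect_false(identical(make_ilp_gene(sp, seed = 42),
                         make_ilp_gene(sp, seed = 43)))
  expect_error(ilp_gene_spec("aIGF", coding_exon_lengths = c(100L, 63L, 108L, 93L)),
               "reading frame")
  expect_silent(ilp_gene_spec("aIGF",
                              coding_exon_lengths = sp$coding_exon_lengths))
})

test_that("planted genes re-extracted from the genome match the generator", {
  syn <- make_genome(n_clusters = 1, decoy_length = 20000, seed = 5)
  for (tid in names(syn$transcripts)) {
    cds <- spliced_cds(syn$genome, syn$features, tid)
    expect_identical(cds, unname(syn$transcripts[tid]))
  }
  # truth intergenic distances are exactly as requested
  gt <- syn$gene_table[order(syn$gene_table$start), ]
  gaps <- gt$start[-1] - gt$end[-nrow(gt)] - 1L
  expect_equal(gaps, c(15000L, 30000L))
})

test_that("pure-decoy genomes contain no framework precursor", {
  syn <- make_genome(n_clusters = 0, decoy_length = 100000, seed = 7)
  expect_equal(nrow(syn$features), 0L)
  hits <- detect_precursors(syn$genome, alphabet = "dna", min_aa = 60,
                            longest_only = TRUE)
  expect_equal(nrow(hits), 0L)
})

test_that("simulated error-free mates are exact substrings of their origin", {
  g <- make_ilp_gene(ilp_gene_spec("aIGF"), seed = 2)
  sim <- simulate_reads(g$transcripts, abundances = c(2, 1), n_spots = 300,
                        read_length = 80, paired = TRUE, insert = 150,
                        seed = 9)
  expect_equal(nrow(sim$spots), 600L)  # paired: 2 half spots per spot
  expect_equal(length(unique(sim$spots$spot_id)), 300L)
  ok <- mapply(function(seq, tid, off, strand) {
    w <- substring(g$transcripts[[tid]], off, off + 79L)
    if (strand == "-") w <- revcomp(w)
    identical(seq, w)
  }, sim$spots$seq, sim$truth$transcript_id, sim$truth$offset,
  sim$truth$strand)
  expect_true(all(ok))
  # determinism and error injection
  expect_identical(sim, simulate_reads(g$transcripts, c(2, 1), 300,
                                       read_length = 80, paired = TRUE,
                                       insert = 150, seed = 9))
  noisy <- simulate_reads(g$transcripts, c(2, 1), 200, read_length = 80,
                          error_rate = 0.05, seed = 9)
  expect_gt(sum(noisy$spots$seq != simulate_reads(
    g$transcripts, c(2, 1), 200, read_length = 80, seed = 9)$spots$seq), 0)
})

test_that("transcript choice follows the abundance weights", {
  tx <- c(t1 = random_dna_str(500, 1), t2 = random_dna_str(500, 2))
  sim <- simulate_reads(tx, abundances = c(10, 1), n_spots = 11000,
                        read_length = 100, seed = 13)
  n1 <- sum(sim$truth$transcript_id == "t1")
  p <- 10 / 11
  sd3 <- 3 * sqrt(11000 * p * (1 - p))
  expect_lt(abs(n1 - 11000 * p), sd3)
  expect_error(simulate_reads(tx, abundances = c(1, 0), n_spots = 10,
                              read_length = 100, seed = 1), "positive")
  expect_error(simulate_reads(tx, abundances = c(1, 1), n_spots = 10,
                              read_length = 600, seed = 1), "read_length")
})
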