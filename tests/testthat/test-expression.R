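test_that("half-spot counting counts each mate at most once, coding only", {
  cds <- random_dna_str(300, 60)
  utr <- random_dna_str(150, 61)
  spots <- tibble::tibble(
    spot_id = c("s1", "s1", "s2", "s2", "s3", "s3", "s4"),
    mate = c(1L, 2L, 1L, 2L, 1L, 2L, 1L),
    seq = c(substring(cds, 1, 80), revcomp(substring(cds, 200, 280)),  # both mates hit
            substring(cds, 50, 130), random_dna_str(80, 62),           # one mate hits
            random_dna_str(80, 63), random_dna_str(80, 64),            # neither
            substring(utr, 10, 90)))                                   # UTR only
  expect_equal(count_coding_reads(cds, spots), 3L)
  # UTR-only mate is not counted even though it matches the full transcript
  expect_equal(count_coding_reads(paste0(cds, utr), spots), 4L)
  # invariance under spot reordering
  perm <- spots[sample(nrow(spots)), ]
  expect_equal(count_coding_reads(cds, perm), 3L)
  expect_error(count_coding_reads("", spots), "empty")
})

test_that("rpm implements half spots per million spots", {
  expect_equal(rpm(12, 2e6), 6.0)
  expect_equal(rpm(0, 123), 0.0)
  expect_equal(rpm(7, 1e6), 7)
  # linear in the count, inversely proportional to the total
  expect_equal(rpm(30, 1e6), 3 * rpm(10, 1e6))
  expect_equal(rpm(10, 2e6), rpm(10, 1e6) / 2)
  expect_error(rpm(1, 0), "positive")
})

test_that("isoform identifier-set arithmetic partitions counts exactly", {
  got <- isoform_counts_from_sets(c("r1", "r2", "r3"), c("r3", "r4"))
  expect_equal(got, list(a_only = 2L, b_only = 1L, shared = 1L,
                         union_total = 4L))
  same <- isoform_counts_from_sets(c("a", "b"), c("a", "b"))
  expect_equal(same$shared, 2L)
  expect_equal(same$a_only + same$b_only, 0L)
  disj <- isoform_counts_from_sets(c("a", "b"), c("c"))
  expect_equal(disj$shared, 0L)
  expect_equal(disj$union_total, 3L)
  # fuzzed conservation: a_only + b_only + shared == union_total
  set.seed(77)
  for (k in 1:50) {
    a <- sample(letters, sample(0:20, 1), replace = TRUE)
    b <- sample(letters, sample(0:20, 1), replace = TRUE)
    got <- isoform_counts_from_sets(a, b)
    expect_equal(got$a_only + got$b_only + got$shared, got$union_total)
  }
})

test_that("isoform counts on simulated reads equal coordinate-derived truth", {
  sp <- ilp_gene_spec("aIGF")
  g <- make_ilp_gene(sp, seed = 6)
  long <- g$transcripts[[1]]; short <- g$transcripts[[2]]
  exl <- sp$coding_exon_lengths
  P <- exl[1] + exl[2] + sp$alt_splice_offset  # common prefix length
  A <- exl[3] - sp$alt_splice_offset           # alt segment length
  mm <- 32L
  rl <- 90L
  sim <- simulate_reads(g$transcripts, abundances = c(3, 2), n_spots = 400,
                        read_length = rl, seed = 15)
  got <- isoform_specific_counts(long, short, sim$spots, min_match = mm)
  truth_sets <- truth_isoform_sets(long, short, sim$truth, P, A, rl, mm,
                                   long_id = names(g$transcripts)[1])
  want <- isoform_counts_from_sets(truth_sets$a, truth_sets$b)
  expect_equal(got, want)
  # with the shared region dominating, reads shared between isoforms exist
  expect_gt(got$shared, 0L)
  expect_gt(got$a_only, 0L)
})

test_that("fold change handles zero denominators as typed markers", {
  expect_equal(fold_change(61.60, 0.20), 308.0)
  expect_gt(fold_change(61.60, 0.20), 100)
  expect_equal(fold_change(7.30, 7.30), 1.0)
  expect_identical(fold_change(4.10, 0), Inf)
  expect_identical(fold_change(0, 0), NaN)
  expect_error(fold_change(-1, 2))
})

test_that("expression_table computes rpm per archive and gene", {
  g <- make_ilp_gene(ilp_gene_spec("relaxin"), seed = 10)
  bg <- stats::setNames(random_dna_str(600, 70), "background")
  tx <- c(g$transcripts, bg)
  arch <- list(
    high = simulate_reads(tx, c(10, 90), 2000, read_length = 80, seed = 1)$spots,
    low = simulate_reads(tx, c(1, 99), 2000, read_length = 80, seed = 2)$spots)
  tab <- expression_table(c(relaxin = unname(g$transcripts[1])), arch)
  expect_equal(tab$rpm, tab$half_spots * 1e6 / tab$total_spots)
  expect_gt(tab$rpm[tab$archive == "high"], tab$rpm[tab$archive == "low"])
})
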