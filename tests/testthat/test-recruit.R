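test_that("recruitment follows exact seed sharing", {
  params <- recruit_params()
  q <- random_dna_str(120, 5)
  spots <- tibble::tibble(
    spot_id = c("a", "b", "c"), mate = 1L,
    seq = c(paste0(random_dna_str(30, 6), substring(q, 50, 70),
                   random_dna_str(30, 7)),          # exact 21-nt share
            random_dna_str(80, 8),                  # no seed in common
            revcomp(substring(q, 10, 90))))         # minus-strand share
  rec <- recruit_reads(c(q = q), spots, params, alphabet = "dna")
  expect_equal(rec$spot_id, c("a", "c"))

  # protein query against a translated frame
  prot <- "MKCDEFGHWW"
  mate_seq <- paste0("T", "ATGAAATGTGATGAATTTGGT")
  spots2 <- tibble::tibble(spot_id = "x", mate = 1L, seq = mate_seq)
  rec2 <- recruit_reads(c(p = prot), spots2,
                        recruit_params(aa_seed_length = 5), alphabet = "protein")
  expect_equal(rec2$spot_id, "x")
  expect_error(recruit_reads(c(q = "ACGT"), spots, params, "dna"), "seed")
})

test_that("recruit_reads equals the brute-force seed scan", {
  g <- make_ilp_gene(ilp_gene_spec("gonadulin"), seed = 12)
  sim <- simulate_reads(g$transcripts, 1, n_spots = 80, read_length = 60,
                        seed = 3)
  decoys <- tibble::tibble(
    spot_id = sprintf("d%03d", 1:120), mate = 1L,
    seq = vapply(1:120, function(i) random_dna_str(60, 1000 + i), character(1)))
  spots <- rbind(sim$spots, decoys)
  params <- recruit_params()
  q_dna <- stats::setNames(substring(g$transcripts[1], 40, 160), "q")
  expect_equal(recruit_reads(q_dna, spots, params, "dna"),
               brute_recruit(q_dna, spots, params, "dna"))
  q_prot <- stats::setNames(g$proteins[[1]], "qp")
  expect_equal(recruit_reads(q_prot, spots, params, "protein"),
               brute_recruit(q_prot, spots, params, "protein"))
})

test_that("greedy assembly merges overlaps, containments and disjoint reads", {
  one <- assemble_reads(c(r1 = "ACGTACGTAC", r2 = "CGTACGGGGG"),
                        min_overlap = 5)
  expect_equal(one$seq, "ACGTACGTACGGGGG")
  expect_setequal(one$reads[[1]], c("r1", "r2"))

  two <- assemble_reads(c(r1 = "ACGTACGTACGTAAAGG", r2 = "CCCCCGGGGGTTTTTAA"),
                        min_overlap = 5)
  expect_equal(nrow(two), 2L)
  expect_setequal(two$seq, c("ACGTACGTACGTAAAGG", "CCCCCGGGGGTTTTTAA"))

  contained <- assemble_reads(c(r1 = "ACGTACGTACGTAAAGG", r2 = "GTACGTACG"),
                              min_overlap = 5)
  expect_equal(contained$seq, "ACGTACGTACGTAAAGG")
  expect_equal(contained$n_reads, 2L)

  expect_error(assemble_reads(c(r1 = "ACG"), min_overlap = 5), "min_overlap")
})

test_that("assembly uses reverse complements and reports coverage", {
  tx <- random_dna_str(300, 44)
  mates <- c(r1 = substring(tx, 1, 120),
             r2 = revcomp(substring(tx, 80, 210)),
             r3 = substring(tx, 170, 300))
  ctg <- assemble_reads(mates, min_overlap = 31)
  expect_equal(nrow(ctg), 1L)
  expect_true(ctg$seq == tx || ctg$seq == revcomp(tx))
  cov <- ctg$coverage[[1]]
  expect_length(cov, 300L)
  expect_true(all(cov >= 1))
  expect_equal(max(cov), 2L)  # the two overlap windows
  # every supporting read is an exact substring up to reverse complement
  for (r in c("r1", "r2", "r3")) {
    expect_true(grepl(mates[[r]], ctg$seq, fixed = TRUE) ||
                  grepl(revcomp(mates[[r]]), ctg$seq, fixed = TRUE))
  }
})

test_that("mismatch-tolerant assembly merges imperfect overlaps", {
  a <- "ACGTACGTACGATCGATCGA"
  b_exact <- substring(a, 9, 20)
  b <- paste0(sub("T", "A", b_exact), "GGCCGGCCGGCC")  # one mismatch in overlap
  merged <- assemble_reads(c(r1 = a, r2 = b), min_overlap = 10,
                           min_identity = 0.9)
  expect_equal(nrow(merged), 1L)
  strict <- assemble_reads(c(r1 = a, r2 = b), min_overlap = 10,
                           min_identity = 1.0)
  expect_equal(nrow(strict), 2L)
})

test_that("iterative recruitment converges and grows monotonically", {
  tx <- stats::setNames(random_dna_str(900, 99), "tx1")
  tiled <- tile_spots(tx, read_length = 100, step = 5)
  q <- stats::setNames(substring(tx, 421, 480), "q")
  res <- iterate_recruitment(q, tiled$spots, recruit_params(), "dna")
  expect_true(res$converged)
  expect_lte(nrow(res$rounds), 10L)
  expect_false(is.unsorted(res$rounds$n_recruited))
  expect_true(grepl(tx, res$contigs$seq[1], fixed = TRUE) ||
                grepl(revcomp(tx), res$contigs$seq[1], fixed = TRUE))

  # a query sharing no seed recruits nothing and stops after round 1
  none <- iterate_recruitment(stats::setNames(strrep("AC", 30), "q2"),
                              tiled$spots, recruit_params(), "dna")
  expect_equal(nrow(none$recruited), 0L)
  expect_equal(nrow(none$rounds), 1L)
})
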