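test_that("pairwise alignment restores common subsequences optimally", {
  al <- progressive_align(c(a = "ACDEFG", b = "ACEFG"))
  expect_equal(unname(al), c("ACDEFG", "AC-EFG"))
  expect_equal(score_alignment(al), brute_align_score("ACDEFG", "ACEFG"))

  same <- progressive_align(c(x = "MKVLFW", y = "MKVLFW"))
  expect_equal(unname(same), c("MKVLFW", "MKVLFW"))

  # optimality against the exhaustive oracle on random small pairs
  set.seed(21)
  for (k in 1:10) {
    a <- random_protein_str(sample(4:8, 1), 100 + k)
    b <- random_protein_str(sample(4:8, 1), 200 + k)
    al <- progressive_align(c(a = a, b = b))
    expect_equal(score_alignment(al), brute_align_score(a, b))
  }
  expect_error(progressive_align(c(a = "", b = "AC")), "empty")
})

test_that("multiple alignment is deterministic and at least as long as inputs", {
  seqs <- family_panel()[c(1, 4, 6, 8)]
  al <- progressive_align(seqs)
  expect_equal(length(unique(nchar(al))), 1L)
  expect_gte(nchar(al[1]), max(nchar(seqs)))
  expect_identical(al, progressive_align(seqs))
  # degapped rows reproduce the inputs
  expect_equal(gsub("-", "", al), seqs)
})

test_that("filter_columns keeps exactly the low-gap columns in order", {
  aln <- c(r1 = "A-CA", r2 = "AAC-", r3 = "A--A", r4 = "AACA")
  # gap fractions: 0, 0.5, 0.25, 0.25
  expect_equal(unname(filter_columns(aln, 0.4)),
               c("ACA", "AC-", "A-A", "ACA"))
  expect_equal(filter_columns(aln, 1), aln)
  gapless <- c(a = "ACDE", b = "AGDE")
  expect_equal(filter_columns(gapless, 0), gapless)
  expect_error(filter_columns(c(a = "--", b = "AA"), 0.3), "0.3")
})

test_that("p-distance excludes gapped positions", {
  d <- pairwise_distance(c(r1 = "AAAA", r2 = "AAAT"))
  expect_equal(d["r1", "r2"], 0.25)
  expect_equal(pairwise_distance(c(a = "A-AA", b = "AGAA"))["a", "b"], 0)
  expect_equal(pairwise_distance(c(a = "ACGT", b = "ACGT"))["a", "b"], 0)
  expect_error(pairwise_distance(c(a = "A--", b = "-AA")), "comparable")
})

test_that("neighbor joining matches closed forms", {
  lab <- c("A", "B", "C")
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, dimnames = list(lab, lab))
  tr <- neighbor_joining(d)
  bl <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl, c(A = 1, B = 1, C = 3))

  lab4 <- LETTERS[1:4]
  d4 <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, dimnames = list(lab4, lab4))
  tr4 <- neighbor_joining(d4)
  expect_equal(ape::cophenetic.phylo(tr4)[lab4, lab4], d4)
  # topology AB|CD with internal branch 1
  internal <- tr4$edge.length[tr4$edge[, 2] > ape::Ntip(tr4)]
  expect_equal(internal, 1)

  two <- neighbor_joining(matrix(c(0, 3, 3, 0), 2,
                                 dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(sum(two$edge.length), 3)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2,
                                       dimnames = list(c("A", "B"),
                                                       c("A", "B")))),
               "symmetric")
})

test_that("neighbor joining exactly recovers random additive trees", {
  set.seed(31)
  for (k in 1:40) {
    nt <- sample(4:12, 1)
    rt <- ape::rtree(nt, rooted = FALSE)
    rt$edge.length <- round(stats::runif(length(rt$edge.length), 0.1, 2), 3)
    dm <- ape::cophenetic.phylo(rt)
    dm <- dm[sort(rownames(dm)), sort(rownames(dm))]
    mine <- neighbor_joining(dm)
    expect_equal(ape::cophenetic.phylo(mine)[rownames(dm), colnames(dm)], dm,
                 tolerance = 1e-8)
    expect_true(as.numeric(ape::dist.topo(ape::unroot(rt), mine)) == 0)
    # independent cross-check against the reference NJ implementation
    if (k <= 5) {
      ref <- ape::nj(dm)
      expect_true(as.numeric(ape::dist.topo(ref, mine)) == 0)
    }
  }
})

test_that("bootstrap supports are deterministic bipartition frequencies", {
  aln <- c(A = "AAAAAAAACC", B = "AAAAAAAAGG", C = "TTTTTTTTCC",
           D = "TTTTTTTTGG")
  bt <- bootstrap_support(aln, replicates = 50, seed = 7)
  expect_equal(clade_support(bt, c("A", "B")), 1.0)
  sup <- suppressWarnings(as.numeric(bt$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 1))
  bt2 <- bootstrap_support(aln, replicates = 50, seed = 7)
  expect_identical(serialize_tree(bt), serialize_tree(bt2))
  # two-row alignments yield a tree without internal branches
  two <- bootstrap_support(c(A = "ACGT", B = "ACGA"), replicates = 10, seed = 1)
  expect_equal(ape::Ntip(two), 2L)
})

test_that("synthetic gonadulins form a supported clade in the similarity tree", {
  seqs <- family_panel()
  st <- similarity_tree(seqs, replicates = 100, seed = 42)
  gon <- grep("^gonadulin", names(seqs), value = TRUE)
  expect_gte(clade_support(st$tree, gon), 0.9)
})

test_that("transmembrane extraction finds hydrophobic runs in order", {
  p <- paste0(strrep("D", 10), strrep("L", 25), strrep("D", 10))
  tm <- extract_tm_regions(p)
  expect_equal(nrow(tm$spans), 1L)
  expect_lte(tm$spans$start, 11L)
  expect_gte(tm$spans$end, 35L)
  expect_equal(extract_tm_regions(strrep("D", 30))$sequence, "")
  two <- paste0(strrep("D", 10), strrep("L", 22), strrep("D", 15),
                strrep("I", 22), strrep("D", 10))
  tm2 <- extract_tm_regions(two)
  expect_equal(nrow(tm2$spans), 2L)
  expect_true(all(diff(tm2$spans$start) > 0))
  expect_equal(tm2$sequence,
               paste(substring(two, tm2$spans$start, tm2$spans$end),
                     collapse = ""))
})
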