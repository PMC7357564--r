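test_that("find_orfs scans all six frames from ATG to the first stop", {
  orfs <- find_orfs("ATGAAATGCTGA", min_aa = 3)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$aa_sequence, "MKC")
  expect_equal(orfs$strand, "+")
  expect_equal(orfs$frame, 1L)
  expect_equal(c(orfs$source_start, orfs$source_end), c(1L, 12L))

  minus <- find_orfs("TCACATTTTCAT", min_aa = 3)
  expect_equal(minus$aa_sequence, "MKM")
  expect_equal(minus$strand, "-")

  expect_equal(nrow(find_orfs("AAAAAAAAA", min_aa = 1)), 0L)
  expect_error(find_orfs("ACGU", min_aa = 1), "alphabet")

  # coordinates map back to a translatable span
  s <- paste0("CC", "ATGGTGAAATTTCCCGGGTAA", "TT")
  o <- find_orfs(s, min_aa = 5)
  expect_equal(translate_cds(substring(s, o$source_start, o$source_end)),
               o$aa_sequence)
})

test_that("match_framework finds the leftmost six-cysteine arrangement", {
  p <- "ACGGGGGGCGGGGGGGGGGCCGGGCGGGGGGGGCAA"
  m <- match_framework(p)
  expect_equal(m$positions, c(2L, 9L, 20L, 21L, 25L, 34L))
  expect_equal(m$extension, 2L)
  expect_length(m$extra_cys, 0L)

  expect_null(match_framework("ACCGGGGCAAAC"))  # 4 cysteines: no match

  # an extra cysteine in the C-peptide region is rejected by the strict
  # pattern but recorded under the tolerant one
  p7 <- "ACGGGGGGCGGGGCGGGGGCCGGGCGGGGGGGGCAA"
  expect_null(match_framework(p7))
  m7 <- match_framework(p7, framework_pattern(allow_extra_cysteines = TRUE))
  expect_length(m7$extra_cys, 1L)
  expect_equal(m7$positions, c(2L, 9L, 20L, 21L, 25L, 34L))
})

test_that("match_framework agrees with brute-force 6-subset enumeration", {
  set.seed(404)
  alphabet <- c(rep("G", 5), "C", "A", "R", "K", "S", "T", "L")
  for (k in 1:60) {
    n <- sample(40:200, 1)
    p <- paste(sample(alphabet, n, replace = TRUE), collapse = "")
    if (sum(strsplit(p, "")[[1]] == "C") > 12) next
    for (allow in c(FALSE, TRUE)) {
      pat <- framework_pattern(allow_extra_cysteines = allow)
      mine <- match_framework(p, pat)
      oracle <- brute_framework(p, pat)
      if (is.null(oracle)) {
        expect_null(mine)
      } else {
        expect_equal(mine$positions, unname(oracle))
      }
    }
  }
})

test_that("GTV motif detection follows the consensus pattern", {
  expect_equal(unname(detect_gtv_motif("AAGTVAPSFAA")), c(3L, 9L))
  expect_equal(unname(detect_gtv_motif("GTVAPSY")), c(1L, 7L))
  expect_null(detect_gtv_motif("GTAAPSF"))  # V is required
})

test_that("arginine-rich segment detection enforces windows and cysteines", {
  span <- detect_arginine_rich("GGRRKRRCRRRRCRRRGG")
  expect_false(is.null(span))
  expect_lte(span[["start"]], 3L)
  expect_gte(span[["end"]], 16L)
  expect_null(detect_arginine_rich("GGGGGGGG"))
  # basic-rich span with a single cysteine fails required_cys = 2
  expect_null(detect_arginine_rich("GGRRKRRCRRRRRRRRGG"))
  expect_false(is.null(detect_arginine_rich("GGRRKRRCRRRRRRRRGG",
                                            required_cys = 1L)))
})

test_that("signal peptide heuristic follows the stated rule", {
  expect_equal(predict_signal_peptide("MKLLVLLLLLLLAGASDFGAAAA"), 15L)
  expect_null(predict_signal_peptide("MDDEEDDEEKKRRDDEEDDEE"))
  # decision is local to the N-terminus
  base <- "MKLLVLLLLLLLAGASDFGAAAAWWWWWWWWWWWWWWWWW"
  tail1 <- paste0(base, strrep("D", 30))
  tail2 <- paste0(base, strrep("L", 30))
  expect_equal(predict_signal_peptide(tail1), predict_signal_peptide(tail2))
  expect_error(predict_signal_peptide("MKLLVLLLL"), "20")
})

test_that("precursor classification applies rules in order", {
  panel <- ilp_reference_panel()
  aigf <- make_ilp_gene(ilp_gene_spec("aIGF"), seed = 1)$proteins[[1]]
  fw <- match_framework(aigf)
  cl <- classify_precursor(fw, gtv_span = detect_gtv_motif(aigf),
                           arg_span = detect_arginine_rich(aigf),
                           scores = panel_scores(aigf, panel))
  expect_equal(cl$family, "aIGF")

  # rule 2: short extension, high similarity to one reference
  rel <- make_ilp_gene(ilp_gene_spec("relaxin"), seed = 2)$proteins[[1]]
  cl2 <- classify_precursor(match_framework(rel), NULL, NULL,
                            panel_scores(rel, panel))
  expect_equal(cl2$family, "relaxin")

  # rule 3: short extension, all scores low
  fw3 <- list(positions = 1:6, extra_cys = integer(0), extension = 5L)
  cl3 <- classify_precursor(fw3, NULL, NULL,
                            c(insulin = 0.1, relaxin = 0.1))
  expect_equal(cl3$family, "gonadulin-candidate")
  # long extension without motifs and low scores stays unknown
  fw4 <- list(positions = 1:6, extra_cys = integer(0), extension = 80L)
  expect_equal(classify_precursor(fw4, NULL, NULL, c(insulin = 0.1))$family,
               "unknown")
  expect_error(classify_precursor(NULL), "framework")
})

test_that("classification is invariant to reference panel order", {
  panel <- ilp_reference_panel()
  prot <- make_ilp_gene(ilp_gene_spec("gonadulin"), seed = 17)$proteins[[1]]
  fw <- match_framework(prot)
  fams <- vapply(1:5, function(k) {
    set.seed(k)
    classify_precursor(fw, NULL, NULL,
                       panel_scores(prot, panel[sample(names(panel))]))$family
  }, character(1))
  expect_length(unique(fams), 1L)
  # exact ties break by lexicographic family name
  tied <- classify_precursor(list(positions = 1:6, extra_cys = integer(0),
                                  extension = 2L),
                             NULL, NULL, c(relaxin = 0.8, insulin = 0.8))
  expect_equal(tied$family, "insulin")
})

test_that("detector has full recall on generator output", {
  syn <- make_genome(n_clusters = 1, decoy_length = 20000, seed = 23)
  ann <- detect_in_annotation(syn$genome, syn$features)
  expect_equal(nrow(ann), sum(syn$features$type == "mRNA"))
  got <- ann$family[match(syn$gene_table$gene_id,
                          sub("\\.t[12]$", "", ann$mrna))]
  expect_equal(got, syn$gene_table$family)
})
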