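# shared fixtures, built in code at test time

random_dna_str <- function(n, seed) {
  ilpminer:::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n,
                                          replace = TRUE), collapse = ""))
}

random_protein_str <- function(n, seed, alphabet = NULL) {
  if (is.null(alphabet)) {
    alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                  "M", "F", "P", "S", "T", "W", "Y", "V")
  }
  ilpminer:::with_seed(seed, paste(sample(alphabet, n, replace = TRUE),
                                   collapse = ""))
}

# a small family panel of generated precursor proteins for tree tests
family_panel <- function() {
  mk <- function(fam, seed) make_ilp_gene(ilp_gene_spec(fam), seed)$proteins[[1]]
  c(gonadulin_1 = mk("gonadulin", 101), gonadulin_2 = mk("gonadulin", 202),
    gonadulin_3 = mk("gonadulin", 303),
    insulin_1 = mk("insulin", 104), insulin_2 = mk("insulin", 205),
    aIGF_1 = mk("aIGF", 106), aIGF_2 = mk("aIGF", 207),
    relaxin_1 = mk("relaxin", 108), relaxin_2 = mk("relaxin", 209))
}

# brute-force oracle: all 6-subsets of cysteine positions against the gap
# bounds; returns the lexicographically smallest valid position vector
brute_framework <- function(protein, pattern = framework_pattern()) {
  cys <- which(strsplit(protein, "", fixed = TRUE)[[1]] == "C")
  if (length(cys) < 6L) return(NULL)
  combos <- utils::combn(cys, 6L)
  valid <- list()
  for (k in seq_len(ncol(combos))) {
    pos <- combos[, k]
    gaps <- diff(pos) - 1L
    ok <- all(vapply(1:5, function(g) {
      gaps[g] >= pattern$gaps[[g]][1] && gaps[g] <= pattern$gaps[[g]][2]
    }, logical(1)))
    if (ok && !pattern$allow_extra_cysteines) {
      interior <- cys[cys > pos[1] & cys < pos[6]]
      ok <- all(interior %in% pos)
    }
    if (ok) valid[[length(valid) + 1L]] <- pos
  }
  if (!length(valid)) return(NULL)
  m <- do.call(rbind, valid)
  m[do.call(order, as.data.frame(m))[1L], ]
}

# coordinate-level truth for isoform matching: a read matches an isoform iff
# it has >= mm consecutive bases inside a region identical between the two
# isoforms (or originates from it). The identical region extends past the
# splice junction by the length of any coincidental base agreement there, so
# the junction flanks are measured on the actual sequences.
truth_isoform_sets <- function(long, short, truth, P, A, rl, mm = 32L,
                               long_id) {
  lcp <- function(a, b) {
    n <- min(nchar(a), nchar(b))
    if (n == 0L) return(0L)
    ca <- strsplit(substring(a, 1, n), "")[[1]]
    cb <- strsplit(substring(b, 1, n), "")[[1]]
    d <- which(ca != cb)
    if (!length(d)) n else d[1L] - 1L
  }
  revstr <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  # right extension of the common prefix past the junction
  j1 <- lcp(substring(long, P + 1), substring(short, P + 1))
  # left extension of the common suffix before the junction
  j2 <- lcp(revstr(substring(long, 1, P + A)), revstr(substring(short, 1, P)))
  a_set <- character(0); b_set <- character(0)
  for (i in seq_len(nrow(truth))) {
    s <- truth$offset[i]; e <- s + rl - 1L
    id <- paste0(truth$read_id[i], "/", truth$mate[i])
    if (truth$transcript_id[i] == long_id) {
      a_set <- c(a_set, id)
      if (min(e, P + j1) - s + 1L >= mm ||
          e - max(s, P + A + 1L - j2) + 1L >= mm) {
        b_set <- c(b_set, id)
      }
    } else {
      b_set <- c(b_set, id)
      if (min(e, P + j1) - s + 1L >= mm ||
          e - max(s, P + 1L - j2) + 1L >= mm) {
        a_set <- c(a_set, id)
      }
    }
  }
  list(a = a_set, b = b_set)
}

# manual codon-table translation and reverse complement, independent of the
# package's Biostrings-based paths
oracle_translate <- function(s) {
  n_cod <- nchar(s) %/% 3L
  if (n_cod < 1L) return("")
  codons <- substring(s, seq(1L, by = 3L, length.out = n_cod),
                      seq(3L, by = 3L, length.out = n_cod))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# brute-force recruitment oracle: test every seed position directly
brute_recruit <- function(query, spots, params, alphabet) {
  k <- if (alphabet == "dna") params$nt_seed_length else params$aa_seed_length
  qmers <- unique(unlist(lapply(query, function(q) {
    substring(q, seq_len(nchar(q) - k + 1L), k:nchar(q))
  })))
  hit <- logical(nrow(spots))
  for (i in seq_len(nrow(spots))) {
    s <- spots$seq[i]
    targets <- if (alphabet == "dna") {
      c(s, oracle_revcomp(s))
    } else {
      unlist(lapply(c(s, oracle_revcomp(s)), function(str) {
        vapply(1:3, function(f) oracle_translate(substring(str, f)),
               character(1))
      }))
    }
    for (t in targets) {
      if (nchar(t) < k) next
      mers <- substring(t, seq_len(nchar(t) - k + 1L), k:nchar(t))
      if (any(mers %in% qmers)) { hit[i] <- TRUE; break }
    }
  }
  out <- unique(spots[hit, c("spot_id", "mate")])
  out[order(out$spot_id, out$mate), ]
}

# exhaustive affine-gap pairwise alignment score (oracle for tiny strings);
# gap of length L costs open + ext * L. f(i, j, right) = best score of
# aligning the prefixes a[1..i], b[1..j] given the state of the column to the
# right; a gap run's `open` is charged at its rightmost column.
brute_align_score <- function(a, b, open = 10, ext = 0.5) {
  B <- ilpminer:::blosum62()
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  memo <- new.env(parent = emptyenv())
  f <- function(i, j, right) {
    if (i == 0L && j == 0L) return(0)
    key <- paste(i, j, right)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    best <- -Inf
    if (i > 0L && j > 0L) {
      best <- max(best, f(i - 1L, j - 1L, "M") + B[ca[i], cb[j]])
    }
    if (i > 0L) {
      best <- max(best,
                  f(i - 1L, j, "X") - ext - (if (right != "X") open else 0))
    }
    if (j > 0L) {
      best <- max(best,
                  f(i, j - 1L, "Y") - ext - (if (right != "Y") open else 0))
    }
    memo[[key]] <- best
    best
  }
  f(length(ca), length(cb), "end")
}

# score an existing 2-row alignment under the same affine convention
score_alignment <- function(aln, open = 10, ext = 0.5) {
  B <- ilpminer:::blosum62()
  m <- do.call(rbind, strsplit(unname(aln), "", fixed = TRUE))
  score <- 0
  in_gap <- c(FALSE, FALSE)
  for (k in seq_len(ncol(m))) {
    a <- m[1, k]; b <- m[2, k]
    if (a != "-" && b != "-") {
      score <- score + B[a, b]
      in_gap[] <- FALSE
    } else if (a == "-") {
      score <- score - ext - (if (in_gap[1]) 0 else open)
      in_gap <- c(TRUE, FALSE)
    } else {
      score <- score - ext - (if (in_gap[2]) 0 else open)
      in_gap <- c(FALSE, TRUE)
    }
  }
  score
}
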