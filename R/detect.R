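# Kyte-Doolittle hydropathy scale
KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

AA20 <- names(KD_SCALE)

#' Cysteine framework spacing pattern
#'
#' Describes the canonical insulin arrangement of six cysteines (two in the
#' B chain, four in the A chain) as five inter-cysteine gap intervals: the
#' number of non-cysteine-constrained residues strictly between consecutive
#' framework cysteines. The defaults encode the insulin fold: B-chain pair
#' 5-40 apart, B-to-A gap 5-200 (the C peptide), the adjacent CC pair (gap 0),
#' then exactly 3 residues to the fifth cysteine and 6-30 to the sixth.
#'
#' @param gaps List of 5 numeric `c(min, max)` gap bounds.
#' @param allow_extra_cysteines Record (rather than reject) extra interior
#'   cysteines, as in the seven-cysteine decapod relaxins.
#' @return An object of class `framework_pattern`.
#' @export
framework_pattern <- function(gaps = list(c(5, 40), c(5, 200), c(0, 0), c(3, 3), c(6, 30)),
                              allow_extra_cysteines = FALSE) {
  stopifnot(length(gaps) == 5L)
  for (g in gaps) {
    stopifnot(length(g) == 2L, g[1] >= 0, g[1] <= g[2])
  }
  structure(list(gaps = gaps, allow_extra_cysteines = allow_extra_cysteines),
            class = "framework_pattern")
}

framework_regex <- function(pattern) {
  cls <- if (pattern$allow_extra_cysteines) "." else "[^C]"
  paste0("C", paste(vapply(pattern$gaps, function(g) {
    paste0(cls, "{", g[1], ",", g[2], "}C")
  }, character(1)), collapse = ""))
}

#' Match the six-cysteine insulin framework in a protein
#'
#' Finds the leftmost set of six cysteines whose consecutive gaps satisfy the
#' pattern bounds ("leftmost" = lexicographically smallest position vector).
#' When `pattern$allow_extra_cysteines` is `TRUE`, additional cysteines lying
#' between framework cysteines are recorded rather than rejected.
#'
#' @param protein Amino-acid string.
#' @param pattern A [framework_pattern()].
#' @return `NULL` when there is no match; otherwise a list with `positions`
#'   (the six framework cysteines, 1-based), `extra_cys` (interior
#'   non-framework cysteine positions) and `extension` (number of residues
#'   after the sixth framework cysteine).
#' @export
match_framework <- function(protein, pattern = framework_pattern()) {
  stopifnot(is.character(protein), length(protein) == 1L)
  if (!grepl(framework_regex(pattern), protein, perl = TRUE)) return(NULL)
  cys <- which(strsplit(protein, "", fixed = TRUE)[[1]] == "C")
  pos <- framework_dfs(cys, pattern$gaps, pattern$allow_extra_cysteines)
  if (is.null(pos)) return(NULL)
  extra <- cys[cys > pos[1] & cys < pos[6] & !(cys %in% pos)]
  list(positions = pos,
       extra_cys = extra,
       extension = nchar(protein) - pos[6])
}

# depth-first search for the lexicographically smallest valid 6-subset of
# cysteine positions; when extras are disallowed, consecutive framework
# cysteines must also be consecutive in the full cysteine list
framework_dfs <- function(cys, gaps, allow_extra) {
  n <- length(cys)
  if (n < 6L) return(NULL)
  rec <- function(level, chosen, last_idx) {
    if (level > 6L) return(chosen)
    idx_range <- if (level == 1L) seq_len(n) else {
      if (last_idx >= n) return(NULL)
      seq.int(last_idx + 1L, n)
    }
    for (i in idx_range) {
      if (level > 1L) {
        gap <- cys[i] - chosen[level - 1L] - 1L
        g <- gaps[[level - 1L]]
        if (gap > g[2]) break  # positions sorted: later ones only larger
        if (gap < g[1]) next
        if (!allow_extra && i != last_idx + 1L) next
      }
      res <- rec(level + 1L, c(chosen, cys[i]), i)
      if (!is.null(res)) return(res)
    }
    NULL
  }
  rec(1L, integer(0), 0L)
}

#' Find open reading frames in a nucleotide sequence
#'
#' Scans all six frames; an ORF runs from an ATG to the first in-frame stop
#' codon (ORFs without a terminating stop are not reported). Nested ATGs
#' within the same stop-delimited fragment yield distinct ORFs unless
#' `longest_only = TRUE`.
#'
#' @param seq Nucleotide string.
#' @param min_aa Minimum protein length (residues, excluding the stop).
#' @param longest_only Report only the 5'-most ORF per stop-delimited
#'   fragment (used for genome-scale scans).
#' @return Tibble with columns `source_start`, `source_end` (1-based inclusive
#'   on the forward strand), `strand`, `frame` and `aa_sequence`.
#' @export
find_orfs <- function(seq, min_aa = 1L, longest_only = FALSE) {
  stopifnot(min_aa >= 1L)
  if (grepl("[^ACGTNacgtn]", seq)) stop("non-nucleotide alphabet in sequence")
  seq <- toupper(seq)
  n <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (frame in 1:3) {
      n_cod <- (n - frame + 1L) %/% 3L
      if (n_cod < min_aa + 1L) next
      aa <- as.character(suppressWarnings(Biostrings::translate(
        Biostrings::DNAString(substring(s, frame, frame + n_cod * 3L - 1L)),
        if.fuzzy.codon = "X", no.init.codon = TRUE)))
      stops <- which(strsplit(aa, "", fixed = TRUE)[[1]] == "*")
      if (!length(stops)) next  # ORFs must end on an in-frame stop
      frag_start <- c(1L, stops[-length(stops)] + 1L)
      frag_stop <- stops
      keep <- frag_stop - frag_start >= min_aa
      frag_start <- frag_start[keep]; frag_stop <- frag_stop[keep]
      if (!length(frag_start)) next
      frags <- substring(aa, frag_start, frag_stop - 1L)
      aa_starts <- vector("list", length(frags))
      if (longest_only) {
        m1 <- regexpr("M", frags, fixed = TRUE)
        sel <- which(m1 > 0L)
        aa_starts[sel] <- as.list(frag_start[sel] + as.integer(m1[sel]) - 1L)
      } else {
        ms <- gregexpr("M", frags, fixed = TRUE)
        for (k in seq_along(frags)) {
          if (ms[[k]][1] > 0L) aa_starts[[k]] <- frag_start[k] + as.integer(ms[[k]]) - 1L
        }
      }
      for (k in seq_along(frags)) {
        starts <- aa_starts[[k]]
        if (is.null(starts)) next
        starts <- starts[frag_stop[k] - starts >= min_aa]
        if (!length(starts)) next
        nt_start_local <- frame + (starts - 1L) * 3L
        nt_end_local <- frame + (frag_stop[k] - 1L) * 3L + 2L  # incl. stop
        if (strand == "+") {
          src_start <- nt_start_local; src_end <- rep(nt_end_local, length(starts))
        } else {
          src_start <- rep(n - nt_end_local + 1L, length(starts))
          src_end <- n - nt_start_local + 1L
        }
        out[[length(out) + 1L]] <- tibble::tibble(
          source_start = src_start, source_end = src_end,
          strand = strand, frame = frame,
          aa_sequence = substring(aa, starts, frag_stop[k] - 1L))
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(source_start = integer(0), source_end = integer(0),
                          strand = character(0), frame = integer(0),
                          aa_sequence = character(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$source_start, res$source_end, res$strand), ]
}

# fast existence test: does any stop-terminated ORF of >= min_aa residues
# contain a framework match? (vectorized; used for decoy hygiene)
has_framework_orf <- function(seq, min_aa = 60L, pattern = framework_pattern()) {
  n <- nchar(seq)
  rx <- framework_regex(pattern)
  for (s in c(seq, revcomp(seq))) {
    for (frame in 1:3) {
      n_cod <- (n - frame + 1L) %/% 3L
      if (n_cod < min_aa + 1L) next
      aa <- as.character(suppressWarnings(Biostrings::translate(
        Biostrings::DNAString(substring(s, frame, frame + n_cod * 3L - 1L)),
        if.fuzzy.codon = "X", no.init.codon = TRUE)))
      frags <- strsplit(aa, "*", fixed = TRUE)[[1]]
      if (!endsWith(aa, "*")) {
        if (length(frags) < 2L) next
        frags <- frags[-length(frags)]  # last fragment lacks a stop codon
      }
      frags <- sub("^[^M]*", "", frags)  # ORF starts at the first M
      frags <- frags[nchar(frags) >= min_aa]
      if (length(frags) && any(grepl(rx, frags, perl = TRUE))) return(TRUE)
    }
  }
  FALSE
}

#' Reverse complement of a nucleotide string
#' @param s Nucleotide string.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Locate the aIGF GTVx1Px2(F/Y) motif
#'
#' @param protein Amino-acid string.
#' @return `c(start, end)` of the leftmost occurrence, or `NULL`.
#' @export
detect_gtv_motif <- function(protein) {
  m <- regexpr("GTV.P.[FY]", protein, perl = TRUE)
  if (m == -1L) return(NULL)
  c(start = as.integer(m), end = as.integer(m) + 6L)
}

#' Locate an arginine-rich alternatively spliced segment
#'
#' Searches for the signature of the aIGF alternative exon-3 segment: a
#' stretch rich in basic residues (R/K) carrying two extra cysteines. A
#' candidate span is a maximal run of positions in which every length-`window`
#' sub-window has a basic fraction at or above `basic_fraction`; the span is
#' returned only if it contains at least `required_cys` cysteines. When
#' several spans qualify the longest (leftmost on ties) is returned.
#'
#' @param protein Amino-acid string.
#' @param window Sub-window length (residues).
#' @param basic_fraction Minimum (R+K) fraction per sub-window.
#' @param required_cys Minimum cysteines within the span.
#' @return `c(start, end)` or `NULL`.
#' @export
detect_arginine_rich <- function(protein, window = 10L, basic_fraction = 0.5,
                                 required_cys = 2L) {
  stopifnot(window >= 4L)
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(aa)
  if (n < window) return(NULL)
  basic <- as.integer(aa %in% c("R", "K"))
  wsum <- cumsum(basic)
  wsum <- wsum[window:n] - c(0L, wsum[seq_len(n - window)])
  ok <- wsum >= basic_fraction * window  # ok[i]: window starting at i qualifies
  if (!any(ok)) return(NULL)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  spans <- NULL
  for (k in which(runs$values)) {
    s <- starts[k]; e <- ends[k] + window - 1L
    ncys <- sum(aa[s:e] == "C")
    if (ncys >= required_cys) spans <- rbind(spans, c(s, e))
  }
  if (is.null(spans)) return(NULL)
  best <- order(-(spans[, 2] - spans[, 1]), spans[, 1])[1]
  c(start = spans[best, 1], end = spans[best, 2])
}

#' Heuristic signal-peptide prediction
#'
#' A deterministic hydropathy heuristic (not a trained model): within the
#' first 30 residues, find the first 7-residue window whose mean
#' Kyte-Doolittle hydropathy is at least `core_min`; the cleavage site is the
#' first position after that core window where the residues at -1 and -3
#' (relative to the cleavage) have small neutral side chains (A, G, S, C, T).
#' The decision depends only on the first 40 residues.
#'
#' @param protein Amino-acid string, length >= 20.
#' @param core_min Minimum mean window hydropathy for the hydrophobic core.
#' @return The 1-based position of the last residue of the signal peptide
#'   (cleavage occurs after it), or `NULL` when no core or site is found.
#' @export
predict_signal_peptide <- function(protein, core_min = 1.5) {
  if (nchar(protein) < 20L) stop("protein shorter than 20 residues")
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  h <- unname(KD_SCALE[aa])
  h[is.na(h)] <- 0
  max_start <- min(24L, length(aa) - 6L)
  core <- NA_integer_
  for (i in seq_len(max_start)) {
    if (mean(h[i:(i + 6L)]) >= core_min) { core <- i; break }
  }
  if (is.na(core)) return(NULL)
  small <- c("A", "G", "S", "C", "T")
  p_max <- min(40L, length(aa))
  for (p in seq.int(core + 7L, p_max)) {
    if (p - 3L >= 1L && aa[p - 1L] %in% small && aa[p - 3L] %in% small) {
      return(p - 1L)
    }
  }
  NULL
}

#' Normalized similarity of a protein against a reference panel
#'
#' Global alignment identity (matches / alignment length) against each panel
#' entry, via [Biostrings::pairwiseAlignment()] with BLOSUM62.
#'
#' @param protein Amino-acid string.
#' @param panel Named character vector of reference precursors (names are
#'   family labels).
#' @return Named numeric vector of identities in `[0, 1]`.
#' @export
panel_scores <- function(protein, panel) {
  stopifnot(length(panel) >= 1L, !is.null(names(panel)))
  vapply(panel, function(ref) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(protein), Biostrings::AAString(ref),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global")
    Biostrings::nmatch(al) / Biostrings::nchar(al)
  }, numeric(1))
}

#' Classify an insulin-like precursor into a family
#'
#' Rule order: (1) a long C-terminal extension (at or above `min_ext`
#' residues after the sixth framework cysteine) together with either the
#' GTVx1Px2(F/Y) motif or an arginine-rich segment labels the precursor aIGF;
#' (2) otherwise the best reference-panel identity at or above `s_min` labels
#' it with that reference's family (ties broken by lexicographic family
#' name); (3) otherwise a short-extension orphan is a "gonadulin-candidate"
#' and anything else "unknown".
#'
#' @param framework A match from [match_framework()] (required).
#' @param gtv_span,arg_span Motif spans or `NULL`.
#' @param scores Named numeric vector of panel identities (may be empty).
#' @param min_ext Minimum aIGF extension length (residues).
#' @param s_min Minimum panel identity for a similarity call.
#' @return List with `family` and the inputs echoed
#'   (`extension`, `scores`).
#' @export
classify_precursor <- function(framework, gtv_span = NULL, arg_span = NULL,
                               scores = numeric(0), min_ext = 40L, s_min = 0.5) {
  if (is.null(framework)) stop("classify_precursor requires a framework match")
  ext <- framework$extension
  family <- NULL
  if (ext >= min_ext && (!is.null(gtv_span) || !is.null(arg_span))) {
    family <- "aIGF"
  } else if (length(scores) && max(scores) >= s_min) {
    best <- sort(names(scores)[scores == max(scores)])[1L]  # lexicographic tie-break
    family <- best
  } else if (ext < min_ext) {
    family <- "gonadulin-candidate"
  } else {
    family <- "unknown"
  }
  list(family = family, extension = ext, scores = scores)
}

#' Detect insulin-like precursors in sequences
#'
#' For nucleotide input, ORFs of at least `min_aa` residues are scanned in
#' all six frames; for protein input each sequence is scanned directly.
#' Each framework hit is annotated with signal peptide, motifs and a family
#' call.
#'
#' @param seqs Tibble from [parse_sequences()] or named character vector.
#' @param alphabet `"dna"` or `"protein"`.
#' @param pattern A [framework_pattern()].
#' @param min_aa Minimum ORF length for nucleotide input.
#' @param panel Optional reference panel for similarity classification
#'   (defaults to the package's synthetic archetypes).
#' @param min_ext,s_min Classification thresholds, see [classify_precursor()].
#' @param longest_only Passed to [find_orfs()] for genome-scale scans.
#' @return Tibble of precursor annotations: `source`, `start`, `end`,
#'   `strand`, `protein`, `cys_positions`, `extra_cys`, `extension`,
#'   `signal_end`, `gtv`, `arg_rich`, `family`.
#' @export
detect_precursors <- function(seqs, alphabet = c("dna", "protein"),
                              pattern = framework_pattern(), min_aa = 60L,
                              panel = NULL, min_ext = 40L, s_min = 0.5,
                              longest_only = FALSE) {
  alphabet <- match.arg(alphabet)
  if (is.character(seqs)) {
    seqs <- tibble::tibble(id = names(seqs), residues = unname(seqs))
  }
  if (is.null(panel)) panel <- ilp_reference_panel()
  rows <- list()
  for (i in seq_len(nrow(seqs))) {
    id <- seqs$id[i]
    cands <- if (alphabet == "dna") {
      orfs <- find_orfs(seqs$residues[i], min_aa = min_aa,
                        longest_only = longest_only)
      if (!nrow(orfs)) next
      tibble::tibble(protein = orfs$aa_sequence, start = orfs$source_start,
                     end = orfs$source_end, strand = orfs$strand)
    } else {
      tibble::tibble(protein = seqs$residues[i], start = 1L,
                     end = nchar(seqs$residues[i]), strand = "+")
    }
    hits <- which(grepl(framework_regex(pattern), cands$protein, perl = TRUE))
    for (j in hits) {
      fw <- match_framework(cands$protein[j], pattern)
      if (is.null(fw)) next
      prot <- cands$protein[j]
      gtv <- detect_gtv_motif(prot)
      argr <- detect_arginine_rich(prot)
      sp <- if (nchar(prot) >= 20L) predict_signal_peptide(prot) else NULL
      sc <- panel_scores(prot, panel)
      cl <- classify_precursor(fw, gtv, argr, sc, min_ext = min_ext, s_min = s_min)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        source = id, start = cands$start[j], end = cands$end[j],
        strand = cands$strand[j], protein = prot,
        cys_positions = list(fw$positions), extra_cys = list(fw$extra_cys),
        extension = fw$extension,
        signal_end = if (is.null(sp)) NA_integer_ else sp,
        gtv = list(gtv), arg_rich = list(argr), family = cl$family)
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(source = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          protein = character(0), cys_positions = list(),
                          extra_cys = list(), extension = integer(0),
                          signal_end = integer(0), gtv = list(),
                          arg_rich = list(), family = character(0)))
  }
  do.call(rbind, rows)
}

#' Detect precursors in an annotated genome
#'
#' Splices each annotated mRNA's CDS from the genome, translates it, and runs
#' framework detection and classification on the resulting precursor.
#'
#' @param genome Named character vector (or 1-row sequence tibble) of scaffold
#'   sequences.
#' @param features Feature tibble (GFF3-style, with `mRNA` and `CDS` rows).
#' @inheritParams detect_precursors
#' @return Precursor annotation tibble with an `mrna` column.
#' @export
detect_in_annotation <- function(genome, features, pattern = framework_pattern(),
                                 panel = NULL, min_ext = 40L, s_min = 0.5) {
  if (!is.character(genome)) genome <- stats::setNames(genome$residues, genome$id)
  if (is.null(panel)) panel <- ilp_reference_panel()
  mrnas <- features[features$type == "mRNA", ]
  rows <- list()
  for (i in seq_len(nrow(mrnas))) {
    cds <- spliced_cds(genome, features, mrnas$ID[i])
    prot <- translate_cds(cds)
    fw <- match_framework(prot, pattern)
    ann <- detect_precursors(stats::setNames(prot, mrnas$ID[i]),
                             alphabet = "protein", pattern = pattern,
                             panel = panel, min_ext = min_ext, s_min = s_min)
    if (nrow(ann)) {
      ann$mrna <- mrnas$ID[i]
      ann$source <- mrnas$seqid[i]
      rows[[length(rows) + 1L]] <- ann
    }
  }
  if (!length(rows)) return(tibble::tibble())
  do.call(rbind, rows)
}

#' Spliced coding sequence of an annotated mRNA
#'
#' @param genome Named character vector of scaffolds.
#' @param features Feature tibble.
#' @param mrna_id `ID` of the mRNA whose CDS rows to splice.
#' @return The coding nucleotide sequence (stop codon included), 5' to 3'.
#' @export
spliced_cds <- function(genome, features, mrna_id) {
  cds <- features[features$type == "CDS" & !is.na(features$Parent) &
                    features$Parent == mrna_id, ]
  if (!nrow(cds)) stop("no CDS rows for mRNA ", mrna_id)
  cds <- cds[order(cds$start), ]
  chunks <- substring(genome[[cds$seqid[1]]], cds$start, cds$end)
  s <- paste(chunks, collapse = "")
  if (cds$strand[1] == "-") s <- revcomp(s) else s
}

#' Translate a coding sequence (dropping a terminal stop codon)
#' @param cds Nucleotide coding sequence.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds) {
  aa <- as.character(suppressWarnings(Biostrings::translate(
    Biostrings::DNAString(cds), if.fuzzy.codon = "X", no.init.codon = TRUE)))
  sub("\\*$", "", aa)
}
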