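# Synthetic data generator: genomes with planted ilp gene clusters, isoform
# transcripts and simulated reads with complete ground truth.

ILP_FAMILIES <- c("insulin", "aIGF", "gonadulin", "relaxin")

# run code with a private RNG stream, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

AA_NO_CYS <- setdiff(AA20, "C")

# fixed arginine-rich alternatively spliced segment: every 10-residue window
# has >= 80% basic residues and the segment carries the two extra cysteines
ARG_SEGMENT <- "VRRKRRCRRRRKRRCRRKRRRRKR"

GTV_MOTIF_AA <- "GTVAPSF"

# signal peptide used by all archetypes: hydrophobic core then an A-G-A
# cleavage context after residue 15
SIGNAL_AA <- "MKLLLLLLLLVLAGA"

# family geometry: residues before the first framework cysteine (after the
# signal), the two configurable framework gaps, and the extension design
FAMILY_GEOMETRY <- list(
  insulin   = list(b_pre = 3L, gap1 = 12L, cpep = 10L, gap5 = 8L, ext = 4L),
  gonadulin = list(b_pre = 3L, gap1 = 14L, cpep = 38L, gap5 = 9L, ext = 4L),
  relaxin   = list(b_pre = 3L, gap1 = 10L, cpep = 12L, gap5 = 8L, ext = 3L),
  aIGF      = list(b_pre = 3L, gap1 = 12L, cpep = 12L, gap5 = 8L,
                   ext1 = 12L, alt = nchar(ARG_SEGMENT), ext2 = 30L,
                   gtv_at = 10L)  # GTV motif offset within ext2
)

# default sequence divergence from the family archetype, encoding the
# qualitative conservation ordering: relaxin most conserved, gonadulin most
# divergent
FAMILY_DIVERGENCE <- c(insulin = 0.15, aIGF = 0.10, gonadulin = 0.35,
                       relaxin = 0.05)

# deterministic archetype builder: fixed per-family seed so the templates are
# constants of the package
family_template <- function(family, seven_cys = FALSE) {
  g <- FAMILY_GEOMETRY[[family]]
  seed <- 7000L + match(family, ILP_FAMILIES)
  with_seed(seed, {
    filler <- function(n) paste(sample(AA_NO_CYS, n, replace = TRUE), collapse = "")
    cpep <- filler(g$cpep)
    # the extra cysteine sits directly after the second framework cysteine,
    # too close to re-seat a six-cysteine frame of its own
    if (seven_cys) substring(cpep, 2L, 2L) <- "C"
    core <- paste0(filler(g$b_pre), "C", filler(g$gap1), "C", cpep,
                   "CC", filler(3L), "C", filler(g$gap5), "C")
    if (family == "aIGF") {
      ext2 <- paste0(filler(g$gtv_at - 1L), GTV_MOTIF_AA,
                     filler(g$ext2 - g$gtv_at + 1L - nchar(GTV_MOTIF_AA)))
      ext1 <- filler(g$ext1)
      list(signal = SIGNAL_AA, core = core, ext1 = ext1,
           alt = ARG_SEGMENT, ext2 = ext2)
    } else {
      list(signal = SIGNAL_AA, core = core, ext = filler(g$ext))
    }
  })
}

# positions a generated gene may mutate: everything except the signal, the
# framework cysteines, the arginine-rich segment and the GTV motif
mutable_mask <- function(template, family) {
  mask <- lapply(template, function(seg) {
    m <- strsplit(seg, "", fixed = TRUE)[[1]] != "C"
    m
  })
  mask$signal[] <- FALSE
  if (family == "aIGF") {
    mask$alt[] <- FALSE
    g <- FAMILY_GEOMETRY[[family]]
    mask$ext2[g$gtv_at:(g$gtv_at + nchar(GTV_MOTIF_AA) - 1L)] <- FALSE
  }
  mask
}

mutate_template <- function(template, mask, divergence) {
  lapply(names(template), function(nm) {
    aa <- strsplit(template[[nm]], "", fixed = TRUE)[[1]]
    idx <- which(mask[[nm]])
    if (length(idx) && divergence > 0) {
      hit <- idx[stats::runif(length(idx)) < divergence]
      if (length(hit)) aa[hit] <- sample(AA_NO_CYS, length(hit), replace = TRUE)
    }
    paste(aa, collapse = "")
  }) |> stats::setNames(names(template))
}

# codon table for reverse translation
codons_by_aa <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

reverse_translate <- function(aa) {
  chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(a) {
    cs <- codons_by_aa[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1)), collapse = "")
}

random_dna <- function(n, gc = 0.4) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

random_intron <- function(len) {
  stopifnot(len >= 6L)
  paste0("GT", random_dna(len - 4L), "AG")
}

#' Specification of a synthetic ilp gene model
#'
#' The archetype aIGF gene has four coding exons: exons 1-2 encode the
#' insulin core (signal, B chain, C peptide, A chain), exon 3 carries the
#' start of the C-terminal extension with an alternative splice site in its
#' middle (the included downstream segment encodes the arginine-rich stretch
#' with two extra cysteines), and exon 4 encodes the GTVx1Px2(F/Y) motif.
#' Non-aIGF families use two coding exons and have no alternative splice
#' site.
#'
#' @param family One of `"insulin"`, `"aIGF"`, `"gonadulin"`, `"relaxin"`.
#' @param strand `"+"` or `"-"`.
#' @param intron_lengths Intron lengths (nt); recycled to the number needed
#'   (1 for two-exon genes, 3 for aIGF).
#' @param divergence Fraction of non-constrained residues mutated away from
#'   the family archetype.
#' @param seven_cys Relaxin only: plant a seventh cysteine inside the
#'   C peptide (the decapod variant).
#' @param coding_exon_lengths Optional override checked against the design:
#'   must match the derived lengths and respect the reading frame.
#' @return An object of class `ilp_gene_spec`.
#' @export
ilp_gene_spec <- function(family = c("insulin", "aIGF", "gonadulin", "relaxin"),
                          strand = "+", intron_lengths = c(151L, 130L, 175L),
                          divergence = NULL, seven_cys = FALSE,
                          coding_exon_lengths = NULL) {
  family <- match.arg(family)
  stopifnot(strand %in% c("+", "-"))
  if (seven_cys && family != "relaxin") {
    stop("seven_cys is a relaxin framework-tolerance option")
  }
  if (is.null(divergence)) divergence <- unname(FAMILY_DIVERGENCE[family])
  stopifnot(divergence >= 0, divergence < 1)
  g <- FAMILY_GEOMETRY[[family]]
  core_aa <- g$b_pre + 1L + g$gap1 + 1L + g$cpep + 2L + 3L + 1L + g$gap5 + 1L
  sig_aa <- nchar(SIGNAL_AA)
  if (family == "aIGF") {
    # exon1: signal + B + half C-peptide; exon2: rest of the insulin core;
    # exon3: constitutive extension + alternatively spliced segment;
    # exon4: terminal extension + stop codon
    exon1_aa <- sig_aa + g$b_pre + 1L + g$gap1 + 1L + g$cpep %/% 2L
    exon2_aa <- sig_aa + core_aa - exon1_aa
    derived <- c(exon1_aa * 3L, exon2_aa * 3L, (g$ext1 + g$alt) * 3L,
                 g$ext2 * 3L + 3L)
    alt_offset <- g$ext1 * 3L
    n_introns <- 3L
  } else {
    exon1_aa <- sig_aa + g$b_pre + 1L + g$gap1 + 1L + g$cpep %/% 2L
    total_aa <- sig_aa + core_aa + g$ext
    derived <- c(exon1_aa * 3L, (total_aa - exon1_aa) * 3L + 3L)
    alt_offset <- NULL
    n_introns <- 1L
  }
  if (!is.null(coding_exon_lengths)) {
    if (sum(coding_exon_lengths) %% 3L != 0L ||
        !identical(as.integer(coding_exon_lengths), as.integer(derived))) {
      stop("coding exon lengths are not multiple-consistent with the reading frame of the ",
           family, " design (expected ", paste(derived, collapse = ", "), ")")
    }
  }
  introns <- as.integer(rep_len(intron_lengths, n_introns))
  if (any(introns < 20L)) stop("intron lengths must be >= 20 nt")
  structure(list(family = family, strand = strand,
                 coding_exon_lengths = as.integer(derived),
                 intron_lengths = introns,
                 alt_splice_offset = alt_offset,
                 divergence = divergence, seven_cys = seven_cys),
            class = "ilp_gene_spec")
}

#' Generate a synthetic ilp gene
#'
#' Builds a precursor protein from the family archetype (mutated at
#' `spec$divergence`), reverse-translates it with uniformly sampled codons,
#' and lays it out over the spec's coding exons separated by GT..AG introns.
#' aIGF genes yield two transcript isoforms that are byte-identical outside
#' the alternatively spliced exon-3 segment.
#'
#' @param spec An [ilp_gene_spec()].
#' @param seed Integer RNG seed; outputs are a pure function of (spec, seed).
#' @param id Gene identifier used in the feature table.
#' @return List with `gene_seq` (genomic sequence, local 1-based coordinates),
#'   `features` (gene/mRNA/CDS tibble), `transcripts` (named CDS isoforms,
#'   stop codon included), `proteins` (translations, stop dropped) and the
#'   echoed `spec`.
#' @export
make_ilp_gene <- function(spec, seed, id = "gene1") {
  stopifnot(inherits(spec, "ilp_gene_spec"))
  with_seed(seed, {
    tpl <- family_template(spec$family, seven_cys = spec$seven_cys)
    mask <- mutable_mask(tpl, spec$family)
    mut <- mutate_template(tpl, mask, spec$divergence)
    if (spec$family == "aIGF") {
      prot_long <- paste0(mut$signal, mut$core, mut$ext1, mut$alt, mut$ext2)
      prot_short <- paste0(mut$signal, mut$core, mut$ext1, mut$ext2)
      cds_long <- paste0(reverse_translate(prot_long), "TAA")
      exl <- spec$coding_exon_lengths
      # alt segment nucleotides lie at the end of coding exon 3
      alt_nt_start <- exl[1] + exl[2] + spec$alt_splice_offset + 1L
      alt_nt_end <- exl[1] + exl[2] + exl[3]
      cds_short <- paste0(substring(cds_long, 1L, alt_nt_start - 1L),
                          substring(cds_long, alt_nt_end + 1L))
      transcripts <- c(t1 = cds_long, t2 = cds_short)
      proteins <- c(t1 = prot_long, t2 = prot_short)
    } else {
      prot <- paste0(mut$signal, mut$core, mut$ext)
      transcripts <- c(t1 = paste0(reverse_translate(prot), "TAA"))
      proteins <- c(t1 = prot)
    }
    names(transcripts) <- paste0(id, ".", names(transcripts))
    names(proteins) <- names(transcripts)

    exl <- spec$coding_exon_lengths
    introns <- vapply(spec$intron_lengths, random_intron, character(1))
    cds_main <- transcripts[[1]]
    # genomic layout on the plus strand
    pieces <- character(0)
    exon_start <- integer(length(exl)); exon_end <- integer(length(exl))
    pos <- 1L; off <- 0L
    for (k in seq_along(exl)) {
      exon_seq <- substring(cds_main, off + 1L, off + exl[k])
      pieces <- c(pieces, exon_seq)
      exon_start[k] <- pos; exon_end[k] <- pos + exl[k] - 1L
      pos <- pos + exl[k]
      off <- off + exl[k]
      if (k < length(exl)) {
        pieces <- c(pieces, introns[k])
        pos <- pos + nchar(introns[k])
      }
    }
    gene_seq <- paste(pieces, collapse = "")
    L <- nchar(gene_seq)

    feat <- list()
    add <- function(type, s, e, ID, Parent = NA_character_, family = NA_character_) {
      feat[[length(feat) + 1L]] <<- tibble::tibble(
        seqid = "local", source = "ilpminer", type = type,
        start = s, end = e, strand = "+", ID = ID, Parent = Parent,
        family = family)
    }
    add("gene", 1L, L, id, family = spec$family)
    iso_ids <- names(transcripts)
    for (iso in seq_along(iso_ids)) {
      add("mRNA", 1L, L, iso_ids[iso], Parent = id, family = spec$family)
      if (spec$family == "aIGF" && iso == 2L) {
        # short isoform: exon 3 truncated at the alternative splice site
        alt_end3 <- exon_start[3] + spec$alt_splice_offset - 1L
        cds_rows <- rbind(c(exon_start[1], exon_end[1]),
                          c(exon_start[2], exon_end[2]),
                          c(exon_start[3], alt_end3),
                          c(exon_start[4], exon_end[4]))
      } else {
        cds_rows <- cbind(exon_start, exon_end)
      }
      for (r in seq_len(nrow(cds_rows))) {
        add("CDS", cds_rows[r, 1], cds_rows[r, 2],
            paste0(iso_ids[iso], ".cds", r), Parent = iso_ids[iso])
      }
    }
    features <- do.call(rbind, feat)

    if (spec$strand == "-") {
      gene_seq <- revcomp(gene_seq)
      new_start <- L - features$end + 1L
      new_end <- L - features$start + 1L
      features$start <- new_start; features$end <- new_end
      features$strand <- "-"
      features <- features[order(features$start, features$end), ]
    }
    list(gene_seq = gene_seq, features = features, transcripts = transcripts,
         proteins = proteins, spec = spec)
  })
}

#' Generate a synthetic genome with planted ilp gene clusters
#'
#' Each cluster is placed on its own scaffold, flanked and separated by decoy
#' sequence drawn from a 40% GC i.i.d. model. Decoy (and the assembled
#' scaffolds as a whole) are rejection-sampled so that no open reading frame
#' outside the planted genes matches the detector's default six-cysteine
#' framework at its minimum ORF length.
#'
#' @param n_clusters Number of gene clusters (0 gives one pure-decoy
#'   scaffold).
#' @param cluster_composition Character vector of families per cluster (or a
#'   list, one vector per cluster).
#' @param intergenic Intergenic distances (nt) between consecutive coding
#'   regions within a cluster; recycled.
#' @param decoy_length Total decoy length (nt) across the genome.
#' @param seed Integer RNG seed.
#' @param strands Optional strand vector per gene (recycled); sampled when
#'   `NULL`.
#' @param min_aa Detector minimum ORF length used for the decoy-hygiene scan.
#' @param max_tries Resampling attempts before giving up.
#' @return List with `genome` (named scaffold sequences), `features` (truth
#'   GFF3-style tibble with global coordinates), `transcripts`, `proteins`,
#'   `gene_table` (one row per planted gene: id, family, scaffold,
#'   coding start/end, strand, cluster) and `intergenic` (planted distances
#'   per cluster).
#' @export
make_genome <- function(n_clusters = 1L,
                        cluster_composition = c("gonadulin", "aIGF", "relaxin"),
                        intergenic = c(15000L, 30000L),
                        decoy_length = 100000L, seed = 1L, strands = NULL,
                        min_aa = 60L, max_tries = 20L) {
  stopifnot(n_clusters >= 0L)
  if (!is.list(cluster_composition)) {
    cluster_composition <- rep(list(cluster_composition), max(n_clusters, 1L))
  }
  stopifnot(length(cluster_composition) >= n_clusters)
  with_seed(seed, {
    if (n_clusters == 0L) {
      decoy <- clean_decoy(decoy_length, min_aa, max_tries)
      return(list(genome = c(scaffold_1 = decoy),
                  features = empty_features(), transcripts = character(0),
                  proteins = character(0), gene_table = empty_gene_table(),
                  intergenic = list()))
    }
    genome <- character(0)
    all_feat <- list(); all_tr <- character(0); all_prot <- character(0)
    gene_rows <- list(); planted_gaps <- vector("list", n_clusters)
    flank <- max(1000L, decoy_length %/% (2L * n_clusters))
    for (cl in seq_len(n_clusters)) {
      fams <- cluster_composition[[cl]]
      stopifnot(all(fams %in% ILP_FAMILIES))
      gaps <- as.integer(rep_len(intergenic, max(length(fams) - 1L, 0L)))
      scaffold <- paste0("scaffold_", cl)
      genes <- list()
      for (gi in seq_along(fams)) {
        strand <- if (is.null(strands)) sample(c("+", "-"), 1L) else
          rep_len(strands, length(fams))[gi]
        sp <- ilp_gene_spec(fams[gi], strand = strand)
        genes[[gi]] <- make_ilp_gene(
          sp, seed = sample.int(.Machine$integer.max, 1L),
          id = sprintf("c%dg%d_%s", cl, gi, fams[gi]))
      }
      # assemble scaffold: flank + genes with exact intergenic gaps + flank
      seqs <- character(0); pos <- 1L
      lead <- clean_decoy(flank, min_aa, max_tries)
      seqs <- c(seqs, lead); pos <- pos + nchar(lead)
      for (gi in seq_along(genes)) {
        g <- genes[[gi]]
        offset <- pos - 1L
        f <- g$features
        f$seqid <- scaffold
        f$start <- f$start + offset; f$end <- f$end + offset
        all_feat[[length(all_feat) + 1L]] <- f
        gene_rows[[length(gene_rows) + 1L]] <- tibble::tibble(
          gene_id = f$ID[f$type == "gene"], family = fams[gi],
          scaffold = scaffold, start = min(f$start), end = max(f$end),
          strand = g$spec$strand, cluster = cl)
        all_tr <- c(all_tr, g$transcripts)
        all_prot <- c(all_prot, g$proteins)
        seqs <- c(seqs, g$gene_seq); pos <- pos + nchar(g$gene_seq)
        if (gi < length(genes)) {
          gap <- clean_decoy(gaps[gi], min_aa, max_tries)
          seqs <- c(seqs, gap); pos <- pos + nchar(gap)
        }
      }
      seqs <- c(seqs, clean_decoy(flank, min_aa, max_tries))
      genome[scaffold] <- paste(seqs, collapse = "")
      planted_gaps[[cl]] <- gaps
    }
    features <- do.call(rbind, all_feat)
    gene_table <- do.call(rbind, gene_rows)
    out <- list(genome = genome, features = features, transcripts = all_tr,
                proteins = all_prot, gene_table = gene_table,
                intergenic = planted_gaps)
    # genome-level hygiene: no framework ORF outside the planted genes
    for (try in seq_len(max_tries)) {
      fp <- decoy_hits(out, min_aa = min_aa)
      if (nrow(fp) == 0L) return(out)
      # resample the offending scaffold's decoy by rebuilding with a new seed
      out <- make_genome(n_clusters, cluster_composition, intergenic,
                         decoy_length, seed = sample.int(2^31 - 1L, 1L),
                         strands = strands, min_aa = min_aa,
                         max_tries = max_tries - 1L)
      return(out)
    }
    stop("could not generate a framework-free decoy background")
  })
}

empty_features <- function() {
  tibble::tibble(seqid = character(0), source = character(0),
                 type = character(0), start = integer(0), end = integer(0),
                 strand = character(0), ID = character(0),
                 Parent = character(0), family = character(0))
}

empty_gene_table <- function() {
  tibble::tibble(gene_id = character(0), family = character(0),
                 scaffold = character(0), start = integer(0),
                 end = integer(0), strand = character(0), cluster = integer(0))
}

# decoy sequence with no framework-matching ORF at the detector's default
# pattern and the given minimum ORF length
clean_decoy <- function(n, min_aa = 60L, max_tries = 20L) {
  if (n == 0L) return("")
  for (k in seq_len(max_tries)) {
    s <- random_dna(n)
    if (n < 3L * (min_aa + 1L)) return(s)
    if (!has_framework_orf(s, min_aa = min_aa)) return(s)
  }
  stop("could not generate framework-free decoy of length ", n)
}

#' Framework hits outside the planted genes of a synthetic genome
#'
#' Scans the raw genome scaffolds for open reading frames matching the
#' six-cysteine framework and returns those not overlapping any planted gene
#' span — the generator's decoy-hygiene false positives.
#'
#' @param synth Output of [make_genome()].
#' @param min_aa Minimum ORF length.
#' @param pattern A [framework_pattern()].
#' @return Tibble of offending hits (empty for a clean genome).
#' @export
decoy_hits <- function(synth, min_aa = 60L, pattern = framework_pattern()) {
  hits <- detect_precursors(synth$genome, alphabet = "dna", min_aa = min_aa,
                            pattern = pattern, longest_only = TRUE,
                            panel = c(none = "MKLLLLLLLLVLAGA"))
  if (!nrow(hits)) return(hits)
  gt <- synth$gene_table
  keep <- vapply(seq_len(nrow(hits)), function(i) {
    g <- gt[gt$scaffold == hits$source[i], ]
    !any(hits$start[i] <= g$end & hits$end[i] >= g$start)
  }, logical(1))
  hits[keep, ]
}

#' Simulate sequencing reads from transcripts with ground truth
#'
#' Spots (sequencing units) choose a transcript multinomially by abundance
#' weight and a uniform start position. Paired spots emit two mates: mate 1
#' forward, mate 2 reverse-complemented from the other end of an insert.
#' Substitution errors are applied per base at `error_rate`.
#'
#' @param transcripts Named character vector of transcript sequences.
#' @param abundances Positive weights, one per transcript.
#' @param n_spots Number of spots.
#' @param read_length Mate length (nt); must not exceed the shortest
#'   transcript.
#' @param paired Emit two mates per spot?
#' @param error_rate Per-base substitution probability.
#' @param insert Insert length for paired spots (clamped to the transcript).
#' @param seed Integer RNG seed.
#' @return List with `spots` (tibble `spot_id`, `mate`, `seq`) and `truth`
#'   (tibble `read_id`, `transcript_id`, `offset`, `mate`, `strand`).
#' @export
simulate_reads <- function(transcripts, abundances, n_spots,
                           read_length = 100L, paired = FALSE,
                           error_rate = 0, insert = 250L, seed = 1L) {
  stopifnot(length(transcripts) >= 1L, !is.null(names(transcripts)),
            length(abundances) == length(transcripts), n_spots >= 1L)
  if (any(abundances <= 0)) stop("abundance weights must be positive")
  tlen <- nchar(transcripts)
  if (read_length > min(tlen)) stop("read_length exceeds the shortest transcript")
  with_seed(seed, {
    pick <- sample(names(transcripts), n_spots, replace = TRUE,
                   prob = abundances / sum(abundances))
    spot_id <- sprintf("s%06d", seq_len(n_spots))
    tl <- tlen[pick]
    rows <- list()
    if (paired) {
      ins <- pmin(insert, tl)
      ins <- pmax(ins, read_length)
      start1 <- 1L + floor(stats::runif(n_spots) * (tl - ins + 1L))
      start2 <- start1 + ins - read_length
      m1 <- substring(transcripts[pick], start1, start1 + read_length - 1L)
      m2 <- revcomp_many(substring(transcripts[pick], start2,
                                   start2 + read_length - 1L))
      rows$m1 <- tibble::tibble(spot_id = spot_id, mate = 1L, seq = unname(m1),
                                transcript_id = pick, offset = start1,
                                strand = "+")
      rows$m2 <- tibble::tibble(spot_id = spot_id, mate = 2L, seq = m2,
                                transcript_id = pick, offset = start2,
                                strand = "-")
    } else {
      start1 <- 1L + floor(stats::runif(n_spots) * (tl - read_length + 1L))
      m1 <- substring(transcripts[pick], start1, start1 + read_length - 1L)
      rows$m1 <- tibble::tibble(spot_id = spot_id, mate = 1L, seq = unname(m1),
                                transcript_id = pick, offset = start1,
                                strand = "+")
    }
    reads <- do.call(rbind, rows)
    reads <- reads[order(reads$spot_id, reads$mate), ]
    if (error_rate > 0) {
      reads$seq <- vapply(reads$seq, function(s) {
        n <- nchar(s)
        k <- stats::rbinom(1L, n, error_rate)
        if (k == 0L) return(s)
        pos <- sample.int(n, k)
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        ch[pos] <- vapply(ch[pos], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1L)
        }, character(1))
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    list(spots = reads[, c("spot_id", "mate", "seq")],
         truth = tibble::tibble(read_id = reads$spot_id,
                                transcript_id = reads$transcript_id,
                                offset = reads$offset, mate = reads$mate,
                                strand = reads$strand))
  })
}

#' Tiling error-free reads over a transcript
#'
#' Single-end spots starting every `step` nt (the final window is always
#' included), giving even coverage of approximately `read_length / step`.
#'
#' @param transcript Named character of length 1.
#' @param read_length Read length (nt).
#' @param step Start-position step (nt).
#' @return List with `spots` and `truth` tibbles as in [simulate_reads()].
#' @export
tile_spots <- function(transcript, read_length = 100L, step = 3L) {
  stopifnot(length(transcript) == 1L, !is.null(names(transcript)))
  tlen <- nchar(transcript)
  stopifnot(read_length <= tlen)
  starts <- unique(c(seq.int(1L, tlen - read_length + 1L, by = step),
                     tlen - read_length + 1L))
  spots <- tibble::tibble(
    spot_id = sprintf("s%06d", seq_along(starts)), mate = 1L,
    seq = substring(transcript, starts, starts + read_length - 1L))
  list(spots = spots,
       truth = tibble::tibble(read_id = spots$spot_id,
                              transcript_id = names(transcript),
                              offset = starts, mate = 1L, strand = "+"))
}

#' Write simulated reads to FASTQ (mates suffixed /1, /2)
#'
#' @param spots Spot tibble from [simulate_reads()].
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_spots_fastq <- function(spots, path) {
  multi <- any(spots$mate > 1L)
  ids <- if (multi) paste0(spots$spot_id, "/", spots$mate) else spots$spot_id
  write_sequences(tibble::tibble(id = ids, desc = "", residues = spots$seq,
                                 alphabet = "dna"),
                  path, format = "fastq")
}

#' Write a planted-truth table to TSV
#'
#' @param truth Truth tibble from [simulate_reads()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Synthetic reference panel of family archetype precursors
#'
#' The four family archetypes (zero divergence) used as the classifier's
#' reference panel. These are synthetic designs, not natural sequences.
#'
#' @return Named character vector (`insulin`, `aIGF`, `gonadulin`,
#'   `relaxin`).
#' @export
ilp_reference_panel <- function() {
  vapply(stats::setNames(ILP_FAMILIES, ILP_FAMILIES), function(fam) {
    tpl <- family_template(fam)
    if (fam == "aIGF") paste0(tpl$signal, tpl$core, tpl$ext1, tpl$alt, tpl$ext2)
    else paste0(tpl$signal, tpl$core, tpl$ext)
  }, character(1))
}
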