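#' Read sequences from FASTA or FASTQ
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] /
#' [Biostrings::readAAStringSet()] that returns a plain tibble, validates the
#' declared alphabet and rejects duplicated identifiers.
#'
#' @param path Path to a FASTA or FASTQ file.
#' @param alphabet `"dna"` or `"protein"`.
#' @param format `"fasta"` or `"fastq"`; guessed from the file extension when
#'   `NULL`.
#' @return A tibble with columns `id`, `desc`, `residues` and `alphabet`.
#'   For FASTQ input an additional `quality` column holds the quality strings.
#' @export
parse_sequences <- function(path, alphabet = c("dna", "protein"), format = NULL) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) "fastq" else "fasta"
  }
  qual <- NULL
  if (alphabet == "dna") {
    ss <- Biostrings::readDNAStringSet(path, format = format, with.qualities = (format == "fastq"))
    if (format == "fastq") qual <- as.character(S4Vectors::mcols(ss)$qualities)
  } else {
    if (format == "fastq") stop("FASTQ is a nucleotide format; use alphabet = 'dna'")
    ss <- Biostrings::readAAStringSet(path, format = format)
  }
  nm <- names(ss)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  if (anyDuplicated(id)) {
    stop("duplicate sequence id: ", id[duplicated(id)][1L])
  }
  res <- as.character(ss)
  if (any(!nzchar(res))) stop("empty sequence record: ", id[!nzchar(res)][1L])
  out <- tibble::tibble(id = id, desc = desc, residues = unname(res), alphabet = alphabet)
  if (!is.null(qual)) out$quality <- unname(qual)
  out
}

#' Write sequences to FASTA or FASTQ
#'
#' @param seqs Tibble as returned by [parse_sequences()], or a named character
#'   vector of residues.
#' @param path Output path.
#' @param format `"fasta"` or `"fastq"` (the latter requires dna residues; a
#'   `quality` column is used when present, otherwise constant `"I"`).
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (is.character(seqs)) {
    seqs <- tibble::tibble(id = names(seqs), desc = "", residues = unname(seqs),
                           alphabet = "dna")
  }
  stopifnot(all(c("id", "residues") %in% names(seqs)))
  if (anyDuplicated(seqs$id)) stop("duplicate sequence id: ",
                                   seqs$id[duplicated(seqs$id)][1L])
  nm <- ifelse(!is.null(seqs$desc) & nzchar(seqs$desc %||% ""),
               paste(seqs$id, seqs$desc), seqs$id)
  if (format == "fasta") {
    is_prot <- !is.null(seqs$alphabet) && any(seqs$alphabet == "protein")
    ss <- if (is_prot) Biostrings::AAStringSet(seqs$residues) else
      Biostrings::DNAStringSet(seqs$residues)
    names(ss) <- nm
    Biostrings::writeXStringSet(ss, path, format = "fasta")
  } else {
    ss <- Biostrings::DNAStringSet(seqs$residues)
    names(ss) <- nm
    q <- if ("quality" %in% names(seqs)) seqs$quality else
      vapply(nchar(seqs$residues), function(n) strrep("I", n), character(1))
    Biostrings::writeXStringSet(ss, path, format = "fastq",
                                qualities = Biostrings::BStringSet(q))
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Collapse FASTQ mates into read spots
#'
#' A "spot" is one sequencing unit: a single read or a read pair. Mates named
#' with `/1` and `/2` suffixes (or identical identifiers) collapse into one
#' spot with two mates; every mate is one countable "half spot".
#'
#' @param reads Tibble from [parse_sequences()] (FASTQ, dna).
#' @return A tibble with columns `spot_id`, `mate` (1 or 2) and `seq`.
#' @export
as_read_spots <- function(reads) {
  stopifnot(all(c("id", "residues") %in% names(reads)))
  has_suffix <- grepl("/[12]$", reads$id)
  spot_id <- ifelse(has_suffix, sub("/[12]$", "", reads$id), reads$id)
  mate <- rep(1L, length(reads$id))
  mate[has_suffix] <- as.integer(substring(reads$id[has_suffix],
                                           nchar(reads$id[has_suffix])))
  if (anyDuplicated(paste(spot_id, mate))) {
    stop("duplicate (spot, mate) pair: ",
         paste(spot_id, mate)[duplicated(paste(spot_id, mate))][1L])
  }
  n_mates <- table(spot_id)
  if (any(n_mates > 2)) stop("spot with more than 2 mates: ",
                             names(n_mates)[n_mates > 2][1L])
  if (any(!nzchar(reads$residues))) stop("empty mate sequence")
  tibble::tibble(spot_id = spot_id, mate = mate, seq = reads$residues)
}

#' Read a spot table from a FASTQ file
#'
#' Convenience composition of [parse_sequences()] and [as_read_spots()].
#'
#' @inheritParams parse_sequences
#' @param paired Collapse `/1`,`/2` mate suffixes into two-mate spots.
#' @return Spot tibble (`spot_id`, `mate`, `seq`).
#' @export
read_spots <- function(path, paired = TRUE) {
  reads <- parse_sequences(path, alphabet = "dna", format = "fastq")
  if (!paired) {
    return(tibble::tibble(spot_id = reads$id, mate = 1L, seq = reads$residues))
  }
  as_read_spots(reads)
}

#' Parse a GFF3 annotation file
#'
#' Uses [rtracklayer::import()] and validates coordinates, strands and
#' Parent/ID referential integrity.
#'
#' @param path GFF3 file (1-based inclusive coordinates).
#' @param sort Sort features by (seqid, start)?
#' @return A tibble with columns `seqid`, `source`, `type`, `start`, `end`,
#'   `strand`, `ID`, `Parent`, `family`.
#' @export
parse_features <- function(path, sort = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  parent <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(p) if (length(p)) as.character(p)[1L] else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))
  feat <- tibble::tibble(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    source = as.character(md$source %||% rep(".", length(gr))),
    type = as.character(md$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    ID = as.character(md$ID %||% rep(NA_character_, length(gr))),
    Parent = parent,
    family = as.character(md$family %||% rep(NA_character_, length(gr)))
  )
  if (any(feat$start > feat$end)) stop("feature with start > end")
  if (any(feat$strand == "*" & feat$type %in% c("gene", "mRNA", "CDS"))) {
    stop("gene/mRNA/CDS feature with undefined strand")
  }
  known <- feat$ID[!is.na(feat$ID)]
  dangling <- setdiff(feat$Parent[!is.na(feat$Parent)], known)
  if (length(dangling)) stop("Parent not present in file: ", dangling[1L])
  if (sort) feat <- feat[order(feat$seqid, feat$start), ]
  feat
}

#' Write features to GFF3
#'
#' @param feat Feature tibble as returned by [parse_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(feat, path) {
  if (any(feat$start > feat$end)) stop("feature with start > end")
  gr <- GenomicRanges::GRanges(
    seqnames = feat$seqid,
    ranges = IRanges::IRanges(start = feat$start, end = feat$end),
    strand = feat$strand
  )
  md <- S4Vectors::DataFrame(
    source = feat$source %||% rep("ilpminer", nrow(feat)),
    type = feat$type,
    ID = feat$ID
  )
  if (!is.null(feat$Parent)) {
    md$Parent <- S4Vectors::splitAsList(
      feat$Parent[!is.na(feat$Parent)],
      factor(which(!is.na(feat$Parent)), levels = seq_len(nrow(feat)))
    )
  }
  if (!is.null(feat$family)) md$family <- feat$family
  md$phase <- compute_cds_phase(feat)
  S4Vectors::mcols(gr) <- md
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# phase of each CDS row (5'-to-3' within its mRNA); NA for non-CDS rows
compute_cds_phase <- function(feat) {
  phase <- rep(NA_integer_, nrow(feat))
  is_cds <- feat$type == "CDS" & !is.na(feat$Parent)
  for (p in unique(feat$Parent[is_cds])) {
    rows <- which(is_cds & feat$Parent == p)
    ord <- if (feat$strand[rows[1]] == "-") {
      rows[order(-feat$start[rows])]
    } else {
      rows[order(feat$start[rows])]
    }
    lens <- feat$end[ord] - feat$start[ord] + 1L
    before <- c(0L, cumsum(lens)[-length(lens)])
    phase[ord] <- (3L - before %% 3L) %% 3L
  }
  phase
}

#' Serialize a support tree to a Newick string
#'
#' @param tree An [ape::phylo] object; bootstrap supports, when present, are
#'   carried in `node.label`.
#' @return A single Newick string, terminated by `;`.
#' @export
serialize_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::Ntip(tree) < 2) stop("tree must have at least 2 leaves")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels: ", tree$tip.label[duplicated(tree$tip.label)][1L])
  }
  if (any(grepl("[;,()\\s]", tree$tip.label, perl = TRUE))) {
    stop("leaf label contains Newick metacharacters: refusing to corrupt output")
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch lengths")
  }
  ape::write.tree(tree)
}

#' Parse a Newick string or file
#'
#' @param text Newick string (used when `path` is `NULL`).
#' @param path Optional file path.
#' @return An [ape::phylo] object.
#' @export
parse_tree <- function(text = NULL, path = NULL) {
  tr <- if (!is.null(path)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tr)) stop("malformed Newick input")
  tr
}
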