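# Synteny cluster detection: single-linkage chaining of ilp-family loci
# along a scaffold, and labelling of the gonadulin-aIGF-relaxin triplication
# signature.

SYNTENY_FAMILIES <- c("insulin", "aIGF", "gonadulin", "relaxin")

#' Cluster ilp-family gene loci along scaffolds
#'
#' Single-linkage chaining per scaffold: consecutive ilp-family loci whose
#' coding-region gap is at most `max_gap` join one cluster. The gap between
#' loci i and i+1 is `start(i+1) - end(i) - 1` over coding-region extents;
#' overlapping loci get distance 0 (with a warning).
#'
#' @param loci Tibble with columns `gene_id`, `family`, `scaffold`, `start`,
#'   `end`, `strand` (coding-region extents, 1-based inclusive), e.g. the
#'   `gene_table` of [make_genome()] or a summarized [parse_features()] output
#'   via [loci_from_features()].
#' @param max_gap Maximum intergenic distance (nt) joining a cluster.
#' @return Tibble with one row per cluster: `scaffold`, `n_genes`, `families`
#'   (ordered by start), `strands`, `distances` (list column), `label`.
#' @export
cluster_genes <- function(loci, max_gap = 1e6) {
  stopifnot(all(c("gene_id", "family", "scaffold", "start", "end", "strand")
                %in% names(loci)))
  if (any(loci$start > loci$end)) stop("locus with start > end")
  loci <- loci[loci$family %in% SYNTENY_FAMILIES, ]
  if (!nrow(loci)) {
    return(tibble::tibble(scaffold = character(0), n_genes = integer(0),
                          families = list(), gene_ids = list(),
                          strands = list(), distances = list(),
                          label = character(0)))
  }
  loci <- loci[order(loci$scaffold, loci$start, loci$end), ]
  out <- list()
  for (sc in unique(loci$scaffold)) {
    g <- loci[loci$scaffold == sc, ]
    gap <- if (nrow(g) > 1L) g$start[-1L] - g$end[-nrow(g)] - 1L else integer(0)
    if (any(gap < 0L)) {
      warning("overlapping loci on ", sc, "; distance set to 0")
      gap[gap < 0L] <- 0L
    }
    brk <- c(TRUE, gap > max_gap)
    cl <- cumsum(brk)
    for (k in unique(cl)) {
      rows <- which(cl == k)
      dd <- if (length(rows) > 1L) gap[rows[-length(rows)]] else integer(0)
      cluster <- tibble::tibble(
        scaffold = sc, n_genes = length(rows),
        families = list(g$family[rows]), gene_ids = list(g$gene_id[rows]),
        strands = list(g$strand[rows]), distances = list(dd),
        label = NA_character_)
      cluster$label <- classify_cluster(cluster)
      out[[length(out) + 1L]] <- cluster
    }
  }
  do.call(rbind, out)
}

#' Label a synteny cluster
#'
#' `triplication-like` when gonadulin, aIGF and relaxin are all present
#' (the triplication signature); `pair` for exactly the gonadulin + aIGF
#' family set; `tandem-duplication` for two or more loci of a single family;
#' `singleton` for one locus; `other` otherwise.
#'
#' @param cluster One-row cluster tibble from [cluster_genes()] (or any list
#'   with a `families` element).
#' @return Character label.
#' @export
classify_cluster <- function(cluster) {
  fams <- cluster$families
  if (is.list(fams)) fams <- fams[[1L]]
  u <- unique(fams)
  if (all(c("gonadulin", "aIGF", "relaxin") %in% u)) return("triplication-like")
  if (setequal(u, c("gonadulin", "aIGF"))) return("pair")
  if (length(fams) >= 2L && length(u) == 1L) return("tandem-duplication")
  if (length(fams) == 1L) return("singleton")
  "other"
}

#' Gene loci from a feature table
#'
#' Summarizes CDS extents per gene: the coding region spans the min/max over
#' all CDS rows of the gene's mRNAs.
#'
#' @param features Feature tibble from [parse_features()] (gene/mRNA/CDS rows
#'   with `family` on genes).
#' @return Loci tibble suitable for [cluster_genes()].
#' @export
loci_from_features <- function(features) {
  genes <- features[features$type == "gene", ]
  mrna <- features[features$type == "mRNA", ]
  cds <- features[features$type == "CDS", ]
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$ID[i]
    tids <- mrna$ID[!is.na(mrna$Parent) & mrna$Parent == gid]
    gc <- cds[!is.na(cds$Parent) & cds$Parent %in% tids, ]
    if (!nrow(gc)) return(NULL)
    tibble::tibble(gene_id = gid, family = genes$family[i],
                   scaffold = genes$seqid[i], start = min(gc$start),
                   end = max(gc$end), strand = genes$strand[i])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(tibble::tibble(gene_id = character(0), family = character(0),
                          scaffold = character(0), start = integer(0),
                          end = integer(0), strand = character(0)))
  }
  do.call(rbind, rows)
}
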