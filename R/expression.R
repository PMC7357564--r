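# Expression quantification: half-spot counts against coding sequence,
# per-million-spots normalization, and isoform partitioning by read
# identifier sets.
#
# Counting convention (deliberately asymmetric, matching the source data this
# emulates): the numerator counts half spots (mates), while the denominator
# is the number of spots in the archive. For paired-end archives this yields
# RPM values twice those of a per-read normalization.

mate_matches_cds <- function(seq, cds_kmers, k) {
  if (nchar(seq) < k) return(FALSE)
  any(substring(seq, 1:(nchar(seq) - k + 1L), k:nchar(seq)) %in% cds_kmers)
}

cds_kmer_index <- function(cds, k) {
  if (!nzchar(cds)) stop("empty coding sequence")
  if (nchar(cds) < k) stop("coding sequence shorter than min_match")
  unique(c(kmer_set(cds, k), kmer_set(revcomp(cds), k)))
}

#' Identifiers of mates containing coding sequence
#'
#' A mate matches when it shares an exact nucleotide stretch of at least
#' `min_match` with the coding sequence, on either strand.
#'
#' @param cds Coding sequence (no UTR).
#' @param spots Spot tibble (`spot_id`, `mate`, `seq`).
#' @param min_match Minimum exact shared stretch (nt).
#' @return Character vector of `spot_id/mate` keys of matching half spots.
#' @export
matching_half_spots <- function(cds, spots, min_match = 32L) {
  idx <- cds_kmer_index(cds, min_match)
  hit <- vapply(spots$seq, mate_matches_cds, logical(1), cds_kmers = idx,
                k = min_match, USE.NAMES = FALSE)
  paste0(spots$spot_id[hit], "/", spots$mate[hit])
}

#' Count half spots containing coding sequence
#'
#' Each mate (half spot) is counted at most once.
#'
#' @inheritParams matching_half_spots
#' @return Integer count of matching half spots.
#' @export
count_coding_reads <- function(cds, spots, min_match = 32L) {
  length(unique(matching_half_spots(cds, spots, min_match)))
}

#' Reads per million spots
#'
#' @param half_spot_count Number of half spots containing coding sequence.
#' @param total_spots Total spots in the archive.
#' @return `half_spot_count * 1e6 / total_spots`.
#' @export
rpm <- function(half_spot_count, total_spots) {
  stopifnot(half_spot_count >= 0)
  if (any(total_spots <= 0)) stop("total_spots must be positive")
  half_spot_count * 1e6 / total_spots
}

#' Isoform-specific half-spot counts by identifier-set arithmetic
#'
#' Matching identifier sets are computed separately for the two isoform
#' coding sequences; identifiers present in both are the shared count and are
#' subtracted from each isoform's initial count.
#'
#' @param cds_a,cds_b Coding sequences of the two splice isoforms.
#' @param spots Spot tibble.
#' @param min_match Minimum exact shared stretch (nt).
#' @return List with `a_only`, `b_only`, `shared`, `union_total`
#'   (`a_only + b_only + shared == union_total` always).
#' @export
isoform_specific_counts <- function(cds_a, cds_b, spots, min_match = 32L) {
  if (identical(cds_a, cds_b)) stop("isoform coding sequences are identical")
  a <- unique(matching_half_spots(cds_a, spots, min_match))
  b <- unique(matching_half_spots(cds_b, spots, min_match))
  isoform_counts_from_sets(a, b)
}

#' Isoform count partition from two identifier sets
#'
#' @param a,b Character vectors of matching identifiers.
#' @return List with `a_only`, `b_only`, `shared`, `union_total`.
#' @export
isoform_counts_from_sets <- function(a, b) {
  a <- unique(a); b <- unique(b)
  shared <- length(intersect(a, b))
  list(a_only = length(a) - shared, b_only = length(b) - shared,
       shared = shared, union_total = length(union(a, b)))
}

#' Expression fold change between two per-million values
#'
#' Zero denominators are real in this kind of survey data (tissues with no
#' detected reads), so they return typed markers rather than raising:
#' `Inf` when only the denominator is zero, `NaN` for 0/0.
#'
#' @param rpm_high,rpm_low Non-negative per-million values.
#' @return `rpm_high / rpm_low`, `Inf`, or `NaN`.
#' @export
fold_change <- function(rpm_high, rpm_low) {
  stopifnot(rpm_high >= 0, rpm_low >= 0)
  if (rpm_low == 0 && rpm_high == 0) return(NaN)
  if (rpm_low == 0) return(Inf)
  rpm_high / rpm_low
}

#' Expression table for genes across archives
#'
#' @param cds_list Named character vector of coding sequences (one per gene).
#' @param archives Named list of spot tibbles (one per archive).
#' @param total_spots Named integer vector of archive spot totals (defaults
#'   to the number of spots in each tibble).
#' @param min_match Minimum exact shared stretch (nt).
#' @return Tibble with columns `archive`, `gene`, `half_spots`, `total_spots`,
#'   `rpm`.
#' @export
expression_table <- function(cds_list, archives, total_spots = NULL,
                             min_match = 32L) {
  stopifnot(!is.null(names(cds_list)), !is.null(names(archives)))
  if (is.null(total_spots)) {
    total_spots <- vapply(archives, function(sp) length(unique(sp$spot_id)),
                          integer(1))
  }
  rows <- list()
  for (ar in names(archives)) {
    ts <- unname(total_spots[[ar]])
    for (g in names(cds_list)) {
      n <- count_coding_reads(cds_list[[g]], archives[[ar]], min_match)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        archive = ar, gene = g, half_spots = n, total_spots = ts,
        rpm = rpm(n, ts))
    }
  }
  do.call(rbind, rows)
}
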