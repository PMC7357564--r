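# Iterative read recruitment and greedy overlap assembly: a desk-scale,
# deterministic re-expression of permissive BLAST recruitment (short exact
# seeds) followed by mini-transcriptome assembly.

#' Recruitment parameters
#'
#' Exact short seeds stand in for permissive E-value BLAST searches: a mate is
#' recruited when it shares at least one exact seed with the query (amino-acid
#' seeds against all six mate translations for protein queries, nucleotide
#' seeds on both strands for nucleotide queries).
#'
#' @param aa_seed_length Amino-acid seed length for protein-query rounds.
#' @param nt_seed_length Nucleotide seed length.
#' @param min_overlap Minimum assembly overlap (nt).
#' @param min_overlap_identity Minimum overlap identity for assembly.
#' @param max_rounds Iteration cap for [iterate_recruitment()].
#' @return An object of class `recruit_params`.
#' @export
recruit_params <- function(aa_seed_length = 4L, nt_seed_length = 21L,
                           min_overlap = 31L, min_overlap_identity = 1.0,
                           max_rounds = 10L) {
  stopifnot(aa_seed_length >= 3L, nt_seed_length >= 11L,
            min_overlap_identity > 0, min_overlap_identity <= 1,
            max_rounds >= 1L, min_overlap >= 1L)
  structure(list(aa_seed_length = as.integer(aa_seed_length),
                 nt_seed_length = as.integer(nt_seed_length),
                 min_overlap = as.integer(min_overlap),
                 min_overlap_identity = min_overlap_identity,
                 max_rounds = as.integer(max_rounds)),
            class = "recruit_params")
}

kmer_set <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1L), k:n))
}

# all six translation frames for a vector of nucleotide strings, batched into
# one translate() call per frame
translate_frames_many <- function(seqs) {
  n <- nchar(seqs)
  out <- rep(list(character(0)), length(seqs))
  fwd <- Biostrings::DNAStringSet(seqs)
  for (str_set in list(fwd, Biostrings::reverseComplement(fwd))) {
    for (f in 1:3) {
      w <- pmax(0L, ((n - f + 1L) %/% 3L) * 3L)
      keep <- which(w >= 3L)
      if (!length(keep)) next
      sub <- Biostrings::subseq(str_set[keep], start = f, width = w[keep])
      aa <- as.character(suppressWarnings(
        Biostrings::translate(sub, if.fuzzy.codon = "X", no.init.codon = TRUE)))
      for (i in seq_along(keep)) {
        out[[keep[i]]] <- c(out[[keep[i]]], aa[i])
      }
    }
  }
  out
}

translate_frames <- function(s) translate_frames_many(s)[[1L]]

#' Recruit read mates sharing an exact seed with a query
#'
#' @param query Query sequence(s) (character vector) — protein or dna; the
#'   mode follows `alphabet`. Later recruitment rounds pass a round's contigs.
#' @param spots Spot tibble (`spot_id`, `mate`, `seq`).
#' @param params A [recruit_params()].
#' @param alphabet `"dna"` or `"protein"`.
#' @return Tibble of recruited `(spot_id, mate)` pairs, duplicate-free.
#' @export
recruit_reads <- function(query, spots, params = recruit_params(),
                          alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  k <- if (alphabet == "dna") params$nt_seed_length else params$aa_seed_length
  if (any(nchar(query) < k)) stop("query shorter than the seed length")
  seeds <- unique(unlist(lapply(query, kmer_set, k = k)))
  if (alphabet == "dna") {
    rc <- revcomp_many(spots$seq)
    hit <- vapply(seq_len(nrow(spots)), function(i) {
      any(c(kmer_set(spots$seq[i], k), kmer_set(rc[i], k)) %in% seeds)
    }, logical(1))
  } else {
    frames <- translate_frames_many(spots$seq)
    hit <- vapply(frames, function(trs) {
      any(unlist(lapply(trs, kmer_set, k = k)) %in% seeds)
    }, logical(1))
  }
  out <- unique(spots[hit, c("spot_id", "mate")])
  out[order(out$spot_id, out$mate), ]
}

#' Greedy overlap assembly of read mates into contigs
#'
#' Reads (and their reverse complements) are merged longest-overlap-first
#' (containments absorbed first), ties broken by the lexicographic pair of
#' contig identifiers. With error-free reads every supporting read is an
#' exact substring of its contig (up to reverse complement). The exact-match
#' path (`min_identity = 1`) anchors candidate overlaps on the partner's
#' `min_overlap`-length prefix; the mismatch-tolerant path scans all pairs
#' directly and is intended for small read sets.
#'
#' @param mates Character vector of nucleotide strings (optionally named;
#'   names become supporting read identifiers).
#' @param min_overlap Minimum overlap length (nt).
#' @param min_identity Minimum overlap identity.
#' @return Tibble with columns `contig_id`, `seq`, `n_reads`, `reads`
#'   (list of supporting read ids) and `coverage` (list of per-base coverage
#'   vectors), longest contig first.
#' @export
assemble_reads <- function(mates, min_overlap = 31L, min_identity = 1.0) {
  if (!length(mates)) {
    return(tibble::tibble(contig_id = character(0), seq = character(0),
                          n_reads = integer(0), reads = list(),
                          coverage = list()))
  }
  if (any(nchar(mates) < min_overlap)) stop("mate shorter than min_overlap")
  if (is.null(names(mates))) names(mates) <- sprintf("r%04d", seq_along(mates))
  if (anyDuplicated(names(mates))) stop("duplicate mate identifiers")
  contigs <- lapply(seq_along(mates), function(i) {
    list(id = names(mates)[i], seq = mates[[i]],
         support = tibble::tibble(read = names(mates)[i], start = 1L,
                                  end = nchar(mates[[i]]), ori = "+"))
  })
  names(contigs) <- vapply(contigs, `[[`, character(1), "id")

  contigs <- if (min_identity >= 1) {
    greedy_merge_exact(contigs, min_overlap)
  } else {
    greedy_merge_approx(contigs, min_overlap, min_identity)
  }

  out <- lapply(seq_along(contigs), function(k) {
    ct <- contigs[[k]]
    cov <- integer(nchar(ct$seq))
    for (r in seq_len(nrow(ct$support))) {
      rng <- ct$support$start[r]:ct$support$end[r]
      cov[rng] <- cov[rng] + 1L
    }
    tibble::tibble(contig_id = sprintf("contig_%03d", k), seq = ct$seq,
                   n_reads = nrow(ct$support), reads = list(ct$support$read),
                   coverage = list(cov))
  })
  res <- do.call(rbind, out)
  res[order(-nchar(res$seq), res$contig_id), ]
}

# ---- exact-overlap greedy assembly -----------------------------------------

#' Batch reverse complement
#' @param x Character vector of nucleotide strings.
#' @return Reverse-complemented strings.
#' @export
revcomp_many <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# candidate store: parallel vectors (i, j, ori, kind, len, pos); an overlap
# candidate means suffix of contig i matches the prefix of contig j (in
# orientation ori), a containment means j lies inside i
empty_cand <- function() {
  list(i = character(0), j = character(0), ori = character(0),
       kind = character(0), len = integer(0), pos = integer(0))
}

cand_bind <- function(...) {
  xs <- list(...)
  list(i = unlist(lapply(xs, `[[`, "i"), use.names = FALSE),
       j = unlist(lapply(xs, `[[`, "j"), use.names = FALSE),
       ori = unlist(lapply(xs, `[[`, "ori"), use.names = FALSE),
       kind = unlist(lapply(xs, `[[`, "kind"), use.names = FALSE),
       len = unlist(lapply(xs, `[[`, "len"), use.names = FALSE),
       pos = unlist(lapply(xs, `[[`, "pos"), use.names = FALSE))
}

cand_subset <- function(cand, keep) {
  lapply(cand, `[`, keep)
}

# map of every contig's min_overlap-length prefix, in both orientations
anchor_map <- function(contigs, mo) {
  ids <- names(contigs)
  pre_f <- vapply(contigs, function(ct) substring(ct$seq, 1L, mo), character(1))
  pre_r <- vapply(contigs, function(ct) substring(ct$rc, 1L, mo), character(1))
  list(prefix = c(pre_f, pre_r), id = c(ids, ids),
       ori = rep(c("+", "-"), each = length(ids)))
}

map_drop <- function(map, ids) {
  keep <- !(map$id %in% ids)
  list(prefix = map$prefix[keep], id = map$id[keep], ori = map$ori[keep])
}

map_add <- function(map, ct, mo) {
  list(prefix = c(map$prefix, substring(ct$seq, 1L, mo), substring(ct$rc, 1L, mo)),
       id = c(map$id, ct$id, ct$id),
       ori = c(map$ori, "+", "-"))
}

# verify an anchored candidate (a's position p against b-in-orientation)
verify_candidates <- function(a_id, aseq, ps, js, oris, contigs, mo) {
  out <- empty_cand()
  la <- nchar(aseq)
  for (k in seq_along(ps)) {
    p <- ps[k]; j <- js[k]; ori <- oris[k]
    if (j == a_id) next
    b <- contigs[[j]]
    bseq <- if (ori == "+") b$seq else b$rc
    lb <- nchar(bseq)
    if (p + lb - 1L <= la) {
      if (substring(aseq, p, p + lb - 1L) == bseq) {
        out <- cand_bind(out, list(i = a_id, j = j, ori = ori,
                                   kind = "contain", len = lb, pos = p))
      }
    } else {
      len <- la - p + 1L
      if (len < lb && substring(aseq, p, la) == substring(bseq, 1L, len)) {
        out <- cand_bind(out, list(i = a_id, j = j, ori = ori,
                                   kind = "overlap", len = len, pos = p))
      }
    }
  }
  out
}

# all candidates with a_id as the left partner, via the anchor map
scan_left <- function(a_id, contigs, map, mo) {
  aseq <- contigs[[a_id]]$seq
  la <- nchar(aseq)
  if (la < mo) return(empty_cand())
  subs <- substring(aseq, 1:(la - mo + 1L), mo:la)
  ps <- integer(0); js <- character(0); oris <- character(0)
  hits <- which(subs %in% map$prefix)
  for (p in hits) {
    ent <- which(map$prefix == subs[p])
    ps <- c(ps, rep(p, length(ent)))
    js <- c(js, map$id[ent])
    oris <- c(oris, map$ori[ent])
  }
  verify_candidates(a_id, aseq, ps, js, oris, contigs, mo)
}

# candidates with a_id as the right partner: occurrences of a_id's prefixes
# inside every other contig
scan_right <- function(a_id, contigs, mo) {
  out <- empty_cand()
  a <- contigs[[a_id]]
  pre <- c(`+` = substring(a$seq, 1L, mo), `-` = substring(a$rc, 1L, mo))
  for (x in setdiff(names(contigs), a_id)) {
    xseq <- contigs[[x]]$seq
    for (ori in c("+", "-")) {
      hits <- gregexpr(pre[[ori]], xseq, fixed = TRUE)[[1]]
      if (hits[1] == -1L) next
      out <- cand_bind(out, verify_candidates(
        x, xseq, as.integer(hits), rep(a_id, length(hits)),
        rep(ori, length(hits)), contigs, mo))
    }
  }
  out
}

greedy_merge_exact <- function(contigs, mo) {
  for (k in seq_along(contigs)) contigs[[k]]$rc <- NA_character_
  rcs <- revcomp_many(vapply(contigs, `[[`, character(1), "seq"))
  for (k in seq_along(contigs)) contigs[[k]]$rc <- rcs[k]
  map <- anchor_map(contigs, mo)
  cand <- empty_cand()
  for (id in names(contigs)) {
    cand <- cand_bind(cand, scan_left(id, contigs, map, mo))
  }
  repeat {
    if (!length(cand$i)) break
    ord <- order(cand$kind != "contain", -cand$len, cand$i, cand$j,
                 cand$ori, cand$pos)
    b1 <- ord[1L]
    best <- list(i = cand$i[b1], j = cand$j[b1], ori = cand$ori[b1],
                 kind = cand$kind[b1], len = cand$len[b1], pos = cand$pos[b1])
    contigs <- merge_contigs(contigs, best)
    contigs[[best$i]]$rc <- revcomp(contigs[[best$i]]$seq)
    keep <- cand$i != best$i & cand$j != best$i &
      cand$i != best$j & cand$j != best$j
    cand <- cand_subset(cand, keep)
    map <- map_drop(map, c(best$i, best$j))
    map <- map_add(map, contigs[[best$i]], mo)
    cand <- cand_bind(cand, scan_left(best$i, contigs, map, mo),
                      scan_right(best$i, contigs, mo))
  }
  for (k in seq_along(contigs)) contigs[[k]]$rc <- NULL
  contigs
}

# ---- mismatch-tolerant greedy assembly (small inputs) ----------------------

best_overlap <- function(a, b, min_overlap, min_id) {
  la <- nchar(a); lb <- nchar(b)
  top <- min(la, lb) - (la == lb && a == b)  # avoid full self-identity trivia
  if (top < min_overlap) return(0L)
  for (len in seq.int(top, min_overlap)) {
    sa <- substring(a, la - len + 1L, la)
    sb <- substring(b, 1L, len)
    mism <- sum(strsplit(sa, "", fixed = TRUE)[[1]] !=
                  strsplit(sb, "", fixed = TRUE)[[1]])
    if (1 - mism / len >= min_id) return(len)
  }
  0L
}

contains_at <- function(a, b, min_id) {
  la <- nchar(a); lb <- nchar(b)
  bb <- strsplit(b, "", fixed = TRUE)[[1]]
  for (p in seq_len(la - lb + 1L)) {
    w <- strsplit(substring(a, p, p + lb - 1L), "", fixed = TRUE)[[1]]
    if (1 - sum(w != bb) / lb >= min_id) return(p)
  }
  NA_integer_
}

greedy_merge_approx <- function(contigs, min_overlap, min_id) {
  repeat {
    if (length(contigs) < 2L) break
    ids <- sort(names(contigs))
    best <- NULL
    for (i in ids) for (j in ids) {
      if (i == j) next
      a <- contigs[[i]]$seq
      for (ori in c("+", "-")) {
        b <- if (ori == "+") contigs[[j]]$seq else revcomp(contigs[[j]]$seq)
        if (nchar(b) <= nchar(a)) {
          pos <- contains_at(a, b, min_id)
          if (!is.na(pos)) {
            best <- better_candidate(best, list(
              len = nchar(b), i = i, j = j, ori = ori, kind = "contain",
              pos = pos))
            next
          }
        }
        len <- best_overlap(a, b, min_overlap, min_id)
        if (len >= min_overlap) {
          best <- better_candidate(best, list(
            len = len, i = i, j = j, ori = ori, kind = "overlap",
            pos = nchar(a) - len + 1L))
        }
      }
    }
    if (is.null(best)) break
    contigs <- merge_contigs(contigs, best)
  }
  contigs
}

better_candidate <- function(best, cand) {
  if (is.null(best)) return(cand)
  if ((cand$kind == "contain") > (best$kind == "contain")) return(cand)
  if ((cand$kind == "contain") < (best$kind == "contain")) return(best)
  if (cand$len > best$len) return(cand)
  if (cand$len < best$len) return(best)
  if (paste(cand$i, cand$j) < paste(best$i, best$j)) cand else best
}

merge_contigs <- function(contigs, m) {
  a <- contigs[[m$i]]; b <- contigs[[m$j]]
  bsup <- b$support
  bseq <- b$seq
  if (m$ori == "-") {
    bseq <- revcomp(bseq)
    lb <- nchar(bseq)
    new_start <- lb - bsup$end + 1L
    bsup$end <- lb - bsup$start + 1L
    bsup$start <- new_start
    bsup$ori <- ifelse(bsup$ori == "+", "-", "+")
  }
  if (m$kind == "contain") {
    off <- m$pos - 1L
    seq <- a$seq
  } else {
    off <- m$pos - 1L
    seq <- paste0(a$seq, substring(bseq, m$len + 1L))
  }
  bsup$start <- bsup$start + off; bsup$end <- bsup$end + off
  merged <- list(id = a$id, seq = seq, support = rbind(a$support, bsup))
  contigs[[m$j]] <- NULL
  contigs[[m$i]] <- merged
  contigs
}

#' Iterative recruitment and assembly
#'
#' Round 1 recruits with the original query; each later round recruits with
#' the previous round's contigs (nucleotide mode). Iteration stops when a
#' round adds no new read identifier, or after `params$max_rounds` rounds.
#' Recruited identifier sets are monotone non-decreasing across rounds.
#'
#' @param query Query sequence (character, length 1), protein or dna.
#' @param spots Spot tibble.
#' @param params A [recruit_params()].
#' @param alphabet Alphabet of the initial query.
#' @return List with `rounds` (per-round tibble: round, n_recruited,
#'   n_contigs, longest_contig), `recruited` (final `(spot_id, mate)`
#'   tibble), `contigs` (final assembly tibble) and `converged`.
#' @export
iterate_recruitment <- function(query, spots, params = recruit_params(),
                                alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  recruited <- tibble::tibble(spot_id = character(0), mate = integer(0))
  contigs <- assemble_reads(character(0))
  log <- list()
  gained <- FALSE
  for (round in seq_len(params$max_rounds)) {
    q <- if (round == 1L) query else contigs$seq
    mode <- if (round == 1L) alphabet else "dna"
    new <- if (round > 1L && !length(q)) recruited[0, ] else
      recruit_reads(q, spots, params, alphabet = mode)
    merged <- unique(rbind(recruited, new))
    gained <- nrow(merged) > nrow(recruited)
    recruited <- merged[order(merged$spot_id, merged$mate), ]
    if (gained) {
      key <- paste(spots$spot_id, spots$mate)
      sel <- spots[key %in% paste(recruited$spot_id, recruited$mate), ]
      contigs <- if (nrow(sel)) {
        assemble_reads(stats::setNames(sel$seq, paste0(sel$spot_id, "/", sel$mate)),
                       params$min_overlap, params$min_overlap_identity)
      } else {
        assemble_reads(character(0))
      }
    }
    log[[round]] <- tibble::tibble(
      round = round, n_recruited = nrow(recruited),
      n_contigs = nrow(contigs),
      longest_contig = if (nrow(contigs)) max(nchar(contigs$seq)) else 0L)
    if (!gained) break
  }
  list(rounds = do.call(rbind, log), recruited = recruited,
       contigs = contigs, converged = !gained)
}
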