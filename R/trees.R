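# Sequence similarity trees: progressive profile alignment over BLOSUM62,
# p-distances, canonical neighbor joining with deterministic tie-breaking,
# and column-bootstrap supports. This is a self-contained stand-in for the
# usual clustal-omega + approximate-ML workflow, adequate for similarity
# grouping (it makes no phylogenetic claims).

aln_to_matrix <- function(aln) {
  stopifnot(is.character(aln), !is.null(names(aln)), length(aln) >= 2L)
  if (length(unique(nchar(aln))) != 1L) stop("alignment rows differ in length")
  do.call(rbind, strsplit(aln, "", fixed = TRUE))
}

matrix_to_aln <- function(m) {
  stats::setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
}

blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

profile_of <- function(rows) {
  # frequency profile over the 20 residues; gaps contribute zero weight
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  sapply(seq_len(ncol(m)), function(j) {
    tab <- table(factor(m[, j], levels = AA20))
    as.numeric(tab) / nrow(m)
  })
}

# affine-gap profile-profile alignment; gap of length L costs open + ext * L
align_profiles <- function(rows_a, rows_b, gap_open, gap_ext) {
  pa <- profile_of(rows_a); pb <- profile_of(rows_b)
  B <- blosum62()[AA20, AA20]
  S <- t(pa) %*% B %*% pb   # column-vs-column substitution scores
  la <- ncol(pa); lb <- ncol(pb)
  NEG <- -1e18
  M <- matrix(NEG, la + 1L, lb + 1L)
  X <- matrix(NEG, la + 1L, lb + 1L)  # gap in B (consume A column)
  Y <- matrix(NEG, la + 1L, lb + 1L)  # gap in A (consume B column)
  M[1, 1] <- 0
  for (i in seq_len(la)) X[i + 1L, 1L] <- -(gap_open + gap_ext * i)
  for (j in seq_len(lb)) Y[1L, j + 1L] <- -(gap_open + gap_ext * j)
  ptrM <- matrix(0L, la + 1L, lb + 1L)
  ptrX <- matrix(0L, la + 1L, lb + 1L)
  ptrY <- matrix(0L, la + 1L, lb + 1L)
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      prev <- c(M[i, j], X[i, j], Y[i, j])
      k <- which.max(prev)
      M[i + 1L, j + 1L] <- prev[k] + S[i, j]
      ptrM[i + 1L, j + 1L] <- k
      xo <- c(M[i, j + 1L] - (gap_open + gap_ext), X[i, j + 1L] - gap_ext)
      k <- which.max(xo)
      X[i + 1L, j + 1L] <- xo[k]; ptrX[i + 1L, j + 1L] <- k
      yo <- c(M[i + 1L, j] - (gap_open + gap_ext), Y[i + 1L, j] - gap_ext)
      k <- which.max(yo)
      Y[i + 1L, j + 1L] <- yo[k]; ptrY[i + 1L, j + 1L] <- k
    }
  }
  fin <- c(M[la + 1L, lb + 1L], X[la + 1L, lb + 1L], Y[la + 1L, lb + 1L])
  state <- which.max(fin)
  score <- fin[state]
  # traceback
  i <- la; j <- lb
  ops <- character(0)
  while (i > 0L || j > 0L) {
    if (i == 0L) { ops <- c("Y", ops); j <- j - 1L; next }
    if (j == 0L) { ops <- c("X", ops); i <- i - 1L; next }
    if (state == 1L) {
      ns <- ptrM[i + 1L, j + 1L]
      ops <- c("M", ops); i <- i - 1L; j <- j - 1L
      state <- ns
    } else if (state == 2L) {
      ns <- c(1L, 2L)[ptrX[i + 1L, j + 1L]]
      ops <- c("X", ops); i <- i - 1L
      state <- ns
    } else {
      ns <- c(1L, 3L)[ptrY[i + 1L, j + 1L]]
      ops <- c("Y", ops); j <- j - 1L
      state <- ns
    }
  }
  ia <- 0L; ib <- 0L
  ca <- strsplit(rows_a, "", fixed = TRUE); cb <- strsplit(rows_b, "", fixed = TRUE)
  na <- length(ops)
  resa <- matrix("-", length(rows_a), na)
  resb <- matrix("-", length(rows_b), na)
  for (k in seq_along(ops)) {
    if (ops[k] != "Y") {
      ia <- ia + 1L
      for (r in seq_along(ca)) resa[r, k] <- ca[[r]][ia]
    }
    if (ops[k] != "X") {
      ib <- ib + 1L
      for (r in seq_along(cb)) resb[r, k] <- cb[[r]][ib]
    }
  }
  list(a = apply(resa, 1L, paste, collapse = ""),
       b = apply(resb, 1L, paste, collapse = ""),
       score = score)
}

#' Progressive multiple alignment of protein sequences
#'
#' Guide tree from 3-mer distances (average linkage), then profile-profile
#' dynamic programming with affine gap penalties and BLOSUM62 substitution
#' scores. Deterministic given its inputs. For two sequences this reduces to
#' an optimal global pairwise alignment under the same scoring.
#'
#' @param seqs Named character vector of protein sequences (>= 2).
#' @param gap_open,gap_ext Affine gap penalties (a gap of length L costs
#'   `gap_open + gap_ext * L`).
#' @return Named character vector of equal-length aligned rows, in input
#'   order.
#' @export
progressive_align <- function(seqs, gap_open = 10, gap_ext = 0.5) {
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
  if (any(!nzchar(seqs))) stop("empty sequence in alignment input")
  if (length(seqs) == 2L) {
    al <- align_profiles(seqs[1L], seqs[2L], gap_open, gap_ext)
    return(stats::setNames(c(al$a, al$b), names(seqs)))
  }
  kd <- kmer_distance(seqs, k = 3L)
  hc <- stats::hclust(stats::as.dist(kd), method = "average")
  groups <- lapply(names(seqs), function(nm) stats::setNames(seqs[nm], nm))
  names(groups) <- names(seqs)
  idx <- stats::setNames(seq_along(seqs), names(seqs))
  node_of <- -seq_along(seqs)  # hclust leaf codes
  cluster_rows <- as.list(seq_along(seqs))
  merged <- vector("list", nrow(hc$merge))
  for (m in seq_len(nrow(hc$merge))) {
    pick <- function(code) {
      if (code < 0L) groups[[names(seqs)[-code]]] else merged[[code]]
    }
    a <- pick(hc$merge[m, 1L]); b <- pick(hc$merge[m, 2L])
    al <- align_profiles(unname(a), unname(b), gap_open, gap_ext)
    merged[[m]] <- stats::setNames(c(al$a, al$b), c(names(a), names(b)))
  }
  final <- merged[[nrow(hc$merge)]]
  final[names(seqs)]
}

kmer_distance <- function(seqs, k = 3L) {
  sets <- lapply(seqs, kmer_set, k = k)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    shared <- length(intersect(sets[[i]], sets[[j]]))
    d[i, j] <- d[j, i] <- 1 - shared / min(length(sets[[i]]), length(sets[[j]]))
  }
  d
}

#' Filter alignment columns by gap fraction
#'
#' Keeps exactly the columns whose gap fraction is at or below
#' `max_gap_fraction`, preserving order. This operationalizes "retain only
#' the well-aligned portion" as a column criterion.
#'
#' @param aln Named character vector of aligned rows.
#' @param max_gap_fraction Threshold in `[0, 1]`.
#' @return Filtered alignment.
#' @export
filter_columns <- function(aln, max_gap_fraction = 0.5) {
  stopifnot(max_gap_fraction >= 0, max_gap_fraction <= 1)
  m <- aln_to_matrix(aln)
  gap_frac <- colMeans(m == "-")
  keep <- gap_frac <= max_gap_fraction
  if (!any(keep)) {
    stop("no column has gap fraction <= ", max_gap_fraction)
  }
  matrix_to_aln(m[, keep, drop = FALSE])
}

#' Pairwise p-distances from an alignment
#'
#' Mismatches over compared positions; positions gapped in either row are
#' excluded. A pair with no comparable positions is an error.
#'
#' @param aln Named character vector of aligned rows.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
pairwise_distance <- function(aln) {
  m <- aln_to_matrix(aln)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok)) {
      stop("no comparable positions between ", rownames(m)[i], " and ",
           rownames(m)[j])
    }
    d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical NJ with the Q criterion; ties are broken by the lexicographic
#' pair of cluster labels (a cluster is labelled by its lexicographically
#' smallest member). Negative branch lengths are clamped to zero with the
#' deficit moved to the sibling branch. Exact on additive matrices.
#'
#' @param d Symmetric non-negative distance matrix with labelled rows.
#' @return An [ape::phylo] tree (unrooted; root trifurcation for >= 3 taxa).
#' @export
neighbor_joining <- function(d) {
  if (is.null(dimnames(d)) || is.null(rownames(d))) stop("distance matrix must be labelled")
  if (!isSymmetric(unname(d), tol = 1e-9)) stop("distance matrix is not symmetric")
  labels <- rownames(d)
  n <- length(labels)
  stopifnot(n >= 2L)
  if (n == 2L) {
    nwk <- sprintf("(%s:%.10g,%s:%.10g);", labels[1], d[1, 2] / 2,
                   labels[2], d[1, 2] / 2)
    return(ape::read.tree(text = nwk))
  }
  nwk <- stats::setNames(labels, labels)       # subtree newick per cluster
  key <- stats::setNames(labels, labels)       # lexicographic cluster key
  D <- d
  active <- labels
  while (length(active) > 3L) {
    r <- length(active)
    Dm <- D[active, active]
    R <- rowSums(Dm)
    Q <- (r - 2) * Dm - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    pairs <- t(apply(cand, 1L, function(ij) sort(c(key[active[ij[1]]],
                                                   key[active[ij[2]]]))))
    ord <- order(pairs[, 1L], pairs[, 2L])
    pick <- cand[ord[1L], ]
    i <- active[pick[1L]]; j <- active[pick[2L]]
    dij <- D[i, j]
    bi <- dij / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- dij - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    u <- paste0("(", nwk[i], ":", format(bi, digits = 12), ",",
                nwk[j], ":", format(bj, digits = 12), ")")
    rest <- setdiff(active, c(i, j))
    du <- (D[i, rest] + D[j, rest] - dij) / 2
    uid <- min(key[i], key[j])
    newD <- matrix(0, length(rest) + 1L, length(rest) + 1L,
                   dimnames = list(c(rest, uid), c(rest, uid)))
    newD[rest, rest] <- D[rest, rest]
    newD[uid, rest] <- du; newD[rest, uid] <- du
    D <- newD
    nwk <- c(nwk[rest], stats::setNames(u, uid))
    key <- c(key[rest], stats::setNames(uid, uid))
    active <- c(rest, uid)
  }
  a <- active[1L]; b <- active[2L]; c3 <- active[3L]
  ba <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  bb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  bc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  ln <- c(ba, bb, bc)
  if (any(ln < 0)) {
    # clamp and spread the deficit over the siblings
    deficit <- sum(pmin(ln, 0))
    ln <- pmax(ln, 0)
    pos <- ln > 0
    ln[pos] <- ln[pos] + deficit / sum(pos)
    ln <- pmax(ln, 0)
  }
  nwk_str <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                     nwk[a], ln[1], nwk[b], ln[2], nwk[c3], ln[3])
  ape::read.tree(text = nwk_str)
}

# canonical bipartition strings for the internal edges of an unrooted tree
tree_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1L]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- character(0)
  nodes <- integer(0)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  for (k in seq_along(pp)) {
    node <- ntip + k
    if (node == root) next
    clade <- labs[pp[[k]]]
    side <- if (ref %in% clade) setdiff(tips, clade) else clade
    if (length(side) < 2L || length(side) > length(tips) - 2L) next
    out <- c(out, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, node)
  }
  stats::setNames(nodes, out)
}

#' Bootstrap supports for a neighbor-joining similarity tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports bipartition frequencies on the full-alignment tree.
#' Deterministic given the seed.
#'
#' @param aln Named character vector of aligned rows.
#' @param replicates Number of bootstrap replicates.
#' @param seed Integer RNG seed.
#' @return The full-alignment NJ tree with supports (fractions in `[0, 1]`)
#'   in `node.label`; trees with two rows have no internal branches and get
#'   no supports.
#' @export
bootstrap_support <- function(aln, replicates = 100L, seed = 1L) {
  stopifnot(replicates >= 1L)
  base <- neighbor_joining(pairwise_distance(aln))
  if (length(aln) <= 3L) return(base)
  bip <- tree_bipartitions(base)
  counts <- stats::setNames(numeric(length(bip)), names(bip))
  m <- aln_to_matrix(aln)
  with_seed(seed, {
    for (r in seq_len(replicates)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      rep_aln <- matrix_to_aln(m[, cols, drop = FALSE])
      tr <- neighbor_joining(pairwise_distance(rep_aln))
      rb <- names(tree_bipartitions(tr))
      hit <- names(counts) %in% rb
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- counts / replicates
  nlab <- character(base$Nnode)
  for (k in seq_along(bip)) {
    nlab[bip[k] - ape::Ntip(base)] <- format(support[k], digits = 3)
  }
  base$node.label <- nlab
  base
}

#' Clade bootstrap support for a set of tips
#'
#' @param tree Tree with supports in `node.label` (from
#'   [bootstrap_support()]).
#' @param tips Tip labels whose exclusive grouping is queried.
#' @return The support of the bipartition separating `tips` from the rest,
#'   or `NA` when the tree does not contain that bipartition.
#' @export
clade_support <- function(tree, tips) {
  all_tips <- sort(tree$tip.label)
  ref <- all_tips[1L]
  side <- sort(tips)
  if (ref %in% side) side <- sort(setdiff(all_tips, side))
  want <- paste(side, collapse = "|")
  bip <- tree_bipartitions(tree)
  if (!(want %in% names(bip))) return(NA_real_)
  node <- bip[[want]]
  as.numeric(tree$node.label[node - ape::Ntip(tree)])
}

#' Sequence similarity tree pipeline
#'
#' Full-precursor progressive alignment (optionally column-filtered), then
#' p-distance, neighbor joining and column-bootstrap supports.
#'
#' @param seqs Named character vector of protein sequences.
#' @param replicates Bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @param max_gap_fraction Optional column filter threshold (`NULL` leaves
#'   the alignment uncurated, the similarity-tree mode).
#' @param gap_open,gap_ext Alignment penalties.
#' @return List with `alignment` and `tree` (supports in `node.label`).
#' @export
similarity_tree <- function(seqs, replicates = 100L, seed = 1L,
                            max_gap_fraction = NULL, gap_open = 10,
                            gap_ext = 0.5) {
  aln <- progressive_align(seqs, gap_open = gap_open, gap_ext = gap_ext)
  if (!is.null(max_gap_fraction)) aln <- filter_columns(aln, max_gap_fraction)
  tree <- bootstrap_support(aln, replicates = replicates, seed = seed)
  list(alignment = aln, tree = tree)
}

#' Extract transmembrane-like regions by hydropathy
#'
#' Maximal runs of positions whose centered Kyte-Doolittle window mean
#' reaches `hydropathy_min`; each run is expanded to the union of its
#' windows and the segments are concatenated in sequence order (the input to
#' transmembrane-only receptor trees).
#'
#' @param protein Amino-acid string (length >= `window`).
#' @param window Centered window length (odd).
#' @param hydropathy_min Minimum mean window hydropathy.
#' @return List with `spans` (tibble `start`, `end`) and `sequence`
#'   (concatenated segments; empty string when none).
#' @export
extract_tm_regions <- function(protein, window = 19L, hydropathy_min = 1.6) {
  stopifnot(window %% 2L == 1L)
  n <- nchar(protein)
  if (n < window) stop("protein shorter than the hydropathy window")
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  h <- unname(KD_SCALE[aa]); h[is.na(h)] <- 0
  hw <- window %/% 2L
  centers <- seq.int(hw + 1L, n - hw)
  means <- vapply(centers, function(c) mean(h[(c - hw):(c + hw)]), numeric(1))
  ok <- means >= hydropathy_min
  if (!any(ok)) {
    return(list(spans = tibble::tibble(start = integer(0), end = integer(0)),
                sequence = ""))
  }
  runs <- rle(ok)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  spans <- list()
  for (k in which(runs$values)) {
    s <- max(1L, centers[starts[k]] - hw)
    e <- min(n, centers[ends[k]] + hw)
    spans[[length(spans) + 1L]] <- tibble::tibble(start = s, end = e)
  }
  spans <- do.call(rbind, spans)
  list(spans = spans,
       sequence = paste(substring(protein, spans$start, spans$end),
                        collapse = ""))
}
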