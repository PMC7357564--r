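# Worked expression contrasts: the published gonadulin ovary survey shipped
# with the package, and a simulated larval archive panel for the
# queen-vs-worker/male contrast.

#' Published gonadulin expression survey
#'
#' Per-million gonadulin expression values across arthropod tissues,
#' transcribed from a published survey table (the package's worked-example
#' input).
#'
#' @return Tibble with columns `species`, `tissue`, `rpm`.
#' @export
gonadulin_survey <- function() {
  path <- system.file("extdata", "gonadulin_expression_survey.tsv",
                      package = "ilpminer", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
}

#' Honeybee queen-ovary gonadulin fold change
#'
#' The reproductive-state contrast computed from the survey: per-million
#' gonadulin expression in the ovary of a normal egg-laying queen over the
#' ovary of a virgin queen.
#'
#' @return The fold change (a single number).
#' @export
queen_ovary_fold_change <- function() {
  sv <- gonadulin_survey()
  bee <- sv[sv$species == "Apis mellifera", ]
  hi <- bee$rpm[bee$tissue == "Ovary of normal egg-laying queen"]
  lo <- bee$rpm[bee$tissue == "Ovary of virgin queen"]
  fold_change(hi, lo)
}

#' Simulated larval-archive gonadulin contrast
#'
#' Builds a synthetic gonadulin gene plus background transcripts, simulates
#' one queen-larva archive and three worker and three male larva archives
#' with a planted gonadulin abundance contrast, quantifies gonadulin RPM in
#' each archive through the counting pipeline, and returns the ratio of the
#' queen archive to the highest non-queen archive.
#'
#' @param seed Integer RNG seed.
#' @param n_spots Spots per archive.
#' @param queen_weight,other_weight Gonadulin abundance weights (background
#'   transcripts take the remaining weight out of 1).
#' @param read_length Read length (nt).
#' @return List with `table` (the per-archive expression tibble) and `ratio`
#'   (queen RPM over the maximum worker/male RPM).
#' @export
larval_gonadulin_contrast <- function(seed = 1L, n_spots = 20000L,
                                      queen_weight = 0.05,
                                      other_weight = 0.002,
                                      read_length = 90L) {
  gon <- make_ilp_gene(ilp_gene_spec("gonadulin"), seed = seed + 1000L,
                       id = "gonadulin")
  bg <- with_seed(seed + 2000L, c(
    bg1 = random_dna(1200, gc = 0.45),
    bg2 = random_dna(900, gc = 0.45),
    bg3 = random_dna(1500, gc = 0.45)))
  tx <- c(gon$transcripts, bg)
  archives <- c(queen_larva = queen_weight,
                worker_larva_1 = other_weight, worker_larva_2 = other_weight,
                worker_larva_3 = other_weight,
                male_larva_1 = other_weight, male_larva_2 = other_weight,
                male_larva_3 = other_weight)
  spots <- lapply(seq_along(archives), function(k) {
    w <- c(archives[k], rep((1 - archives[k]) / 3, 3))
    simulate_reads(tx, abundances = w, n_spots = n_spots,
                   read_length = read_length, seed = seed + 10L * k)$spots
  })
  names(spots) <- names(archives)
  tab <- expression_table(c(gonadulin = unname(gon$transcripts[1])), spots)
  q <- tab$rpm[tab$archive == "queen_larva"]
  others <- tab$rpm[tab$archive != "queen_larva"]
  list(table = tab, ratio = q / max(others))
}
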