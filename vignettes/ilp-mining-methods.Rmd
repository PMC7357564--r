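---
title: "Methods: mining and characterizing arthropod insulin-like peptide genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining and characterizing arthropod insulin-like peptide genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilpminer)
```

## The problem

Arthropod insulin-like peptides (ilps) are secreted precursors built from a
signal peptide, a B chain, a connecting C peptide and an A chain. Four
families matter here: the neuroendocrine insulins; the arthropod insulin-like
growth factors (aIGF), which carry a long C-terminal extension encoded by two
extra exons and alternatively spliced; gonadulin, a highly divergent ilp
expressed notably in gonads; and arthropod relaxin, the most conserved of the
group. Primary sequence conservation across these families is so poor that
standard homology annotation misses them; the one dependable landmark is the
insulin fold's six-cysteine framework, and the one dependable genomic signal
is synteny — in several insect genomes the gonadulin, aIGF and relaxin genes
sit next to one another, the signature of an ancient local gene triplication.

`ilpminer` implements the complete desk-scale workflow around these
landmarks: targeted read recruitment and assembly, framework detection and
family classification, half-spot expression quantification with isoform
partitioning, sequence-similarity trees, and synteny labelling, all
validated against a synthetic-data generator with planted truth.

## Precursor detection

### The framework pattern

A framework match is six cysteines whose five consecutive gaps (residues
strictly between them) fall inside configurable intervals; the defaults are

| gap | bounds | meaning |
|-----|--------|---------|
| 1 | 5–40 | between the two B-chain cysteines |
| 2 | 5–200 | across the C peptide into the A chain |
| 3 | 0 | the adjacent CC pair |
| 4 | 3 | CC to the fifth cysteine |
| 5 | 6–30 | fifth to sixth cysteine |

These bounds encode the canonical insulin fold generously; only the cysteine
count is a hard biological constraint, so every interval is exposed in
`framework_pattern()`. `match_framework()` returns the *leftmost*
(lexicographically smallest) valid position vector, found by depth-first
search over cysteine positions; a brute-force enumeration over all 6-subsets
serves as its test oracle. With `allow_extra_cysteines = TRUE` interior
extra cysteines are recorded instead of rejected — needed for the decapod
relaxin variant carrying a seventh cysteine. The C-terminal *extension* is
the residue count after the sixth framework cysteine; it separates aIGFs
(long extension) from the other families.

### Motifs and signal peptides

Two aIGF diagnostics are detected directly: the `GTVx1Px2(F/Y)` consensus of
the last coding exon (leftmost regex occurrence), and the arginine-rich
alternatively spliced segment — operationalized as a maximal run of
positions in which every 10-residue window has a basic (R+K) fraction of at
least 0.5 and which contains at least 2 cysteines. Window length, fraction
and cysteine count are arguments.

Signal peptides are predicted by a deterministic hydropathy heuristic, not a
trained model (no such model is available offline, and determinism makes the
rule testable): the first 7-residue window within the first 24 positions
whose mean Kyte–Doolittle hydropathy reaches 1.5 is the hydrophobic core;
cleavage falls at the first position after the core whose −1 and −3 residues
are small and neutral (A, G, S, C, T); the search stops at residue 40, so
the decision is strictly N-terminal-local. This is *not* equivalent to a
neural-network predictor and should be read as a plausible cleavage
bookmark, not a validated site. Convertase cleavage of the mature peptides
is deliberately not predicted: gonadulin and aIGF are likely not processed
by neuroendocrine convertases, so convertase rules would not apply.

### Classification

`classify_precursor()` applies three ordered rules: (1) extension ≥ 40
residues plus either aIGF motif → `aIGF`; (2) otherwise the best
reference-panel global-alignment identity ≥ 0.5 names the family (ties
broken lexicographically, so the call is independent of panel order); (3)
otherwise short-extension orphans are labelled `gonadulin-candidate` — a
deliberately hedged label, because no formal rule separates a true gonadulin
from an arbitrary divergent ilp; anything else is `unknown`. The 40-residue
and 0.5 thresholds are package choices, exposed as arguments. The shipped
reference panel consists of the package's four synthetic family archetypes
(see below), not natural sequences.

## Iterative mining

The recruitment loop re-expresses a maximally permissive translated-BLAST
search as exact short seeds: a mate is recruited iff it shares one exact
seed with the query — 4-residue amino-acid seeds against all six mate
translations for protein queries, 21-nt seeds on both strands for nucleotide
queries. Short exact seeds reproduce the intended permissiveness while being
deterministic and oracle-checkable (a brute-force position scan is the test
oracle). Assembly is greedy overlap-layout: candidate overlaps are anchored
on each contig's `min_overlap`-length prefix (default 31 nt), merges proceed
longest-overlap-first with containments absorbed first and ties broken by
the lexicographic contig-id pair; reverse complements are considered
throughout. A mismatch-tolerant path (overlap identity < 1) exists for small
inputs; the default identity is 1.0, matching the error-free regime the
loop is validated in. Iteration recruits with the original query in round 1
and with the growing contigs thereafter, stopping when the recruited
identifier set gains nothing (our convergence proxy for "the transcript is
complete", which is otherwise a subjective call) or after `max_rounds`
(default 10). Recruited sets are monotone non-decreasing by construction.
At ~30× error-free coverage the loop extends a 60-nt seed by up to
read-length − seed-length per flank per round, so a 900-nt transcript
completes in about 6–7 rounds.

## Expression quantification

A *spot* is one sequencing unit (a read pair or single read); each mate is a
*half spot*, the counting unit. A mate contains coding sequence when it
shares an exact stretch of at least `min_match = 32` nt with the CDS on
either strand — exact matching replaces BLAST HSPs to keep the criterion
deterministic; 32 nt is short enough to tolerate desk-scale read lengths and
long enough that chance matches are vanishingly rare. Only coding sequence
is queried, never UTRs, which can share stretches with other genes'
transcripts and inflate counts.

RPM = half-spot count × 10⁶ / total spots. Note the deliberate asymmetry:
the numerator counts half spots while the denominator counts spots, so
paired-end archives yield RPM values twice those of a per-read convention.
This mirrors the convention of the survey data the package ships and is kept
because the worked-example contrasts are computed on that scale.

Isoform partitioning is identifier-set arithmetic: with matching sets A and
B for the two isoform CDSs, `shared = |A∩B|`, `a_only = |A|−shared`,
`b_only = |B|−shared`, `union_total = |A∪B|`; the identity
`a_only + b_only + shared = union_total` holds for all inputs. Defining the
initial counts on identifier *sets* (each identifier once) makes the
shared-read subtraction exact. A structural consequence worth knowing: when
the short isoform is entirely contained in the long isoform's shared
regions, `b_only` is 0 for read lengths ≥ 2×`min_match` − 2 — every
junction-spanning short-isoform read still carries ≥ 32 consecutive shared
bases — so "long-isoform-specific vs total" is the informative contrast.

Fold changes between RPM values return `Inf` when only the denominator is 0
and `NaN` for 0/0, as typed markers rather than errors: zero tissues are
real in survey data.

## Trees

The similarity-tree pipeline aligns *uncurated full precursors* —
progressive profile–profile alignment with BLOSUM62, affine gaps (open 10,
extend 0.5), guide tree from 3-mer distances — then computes p-distances
(gap positions excluded pairwise) and a neighbor-joining tree with
column-bootstrap supports. This replaces the usual clustal-omega +
approximate-ML workflow with a self-contained, deterministic equivalent; the
substitution is intentional and visible. These trees are *similarity*
groupings, not phylogenies: with sequences this divergent no alignment
column can be trusted individually, but the grouping of families (e.g. the
gonadulins against everything else) is robust and is exactly what the
bootstrap supports quantify. Supports here are bipartition frequencies over
column resamples, not SH-like probabilities.

NJ uses the Q criterion with ties broken by the lexicographic pair of
cluster labels; negative branch lengths are clamped to zero with the deficit
moved to the sibling so path lengths are preserved. On additive matrices the
implementation is exact (tested by round-tripping random trees through
their path-length matrices, and cross-checked against an independent NJ
implementation). For filtered trees, `filter_columns()` drops columns whose
gap fraction exceeds a threshold (default 0.5) — "keep the well-aligned
part" read as a *column* criterion; dropping whole sequences instead is
available to the caller by subsetting before alignment, but no default does
so. Transmembrane-only trees take their input from
`extract_tm_regions()`: maximal runs of positions whose centered 19-residue
Kyte–Doolittle window mean reaches 1.6 (the standard TM convention), each
run expanded to the union of its windows, segments concatenated in order.

## Synteny

`cluster_genes()` chains ilp-family loci along a scaffold by single linkage:
consecutive loci join a cluster when the gap between their coding-region
extents (`start(i+1) − end(i) − 1`) is at most `max_gap` (default 1 Mb —
observed intergenic distances in real arrangements are tens to hundreds of
kb, so 1 Mb is safely permissive). Distances are measured between coding
regions, not transcripts. Labels are descriptive only: clusters containing
gonadulin, aIGF and relaxin are `triplication-like` (local aIGF duplications
included), gonadulin+aIGF alone is `pair`, multiple loci of one family is
`tandem-duplication`, one locus is `singleton`. No statistical test of
clustering is implemented because adjacency itself is the claim being
reported, not a probability.

## The synthetic study system

The generator is first-class, tested code — it defines the conditions under
which every pipeline stage is validated.

**Archetypes.** Each family has a fixed synthetic archetype precursor
(signal peptide, framework-bearing core, family-specific extension) built
once from a fixed internal seed — these are designed sequences, not natural
ones. Family geometry: insulin and gonadulin short extensions with
C-peptides of 10 and 38 residues respectively; relaxin a 12-residue
C peptide with an optional seventh cysteine; aIGF a 66-residue extension
comprising a constitutive part, the 24-residue arginine-rich alternatively
spliced segment (two extra cysteines), and a terminal part carrying
`GTVAPSF`. A generated gene mutates a family-specific fraction of
unconstrained residues away from its archetype — relaxin 0.05 < aIGF 0.10 <
insulin 0.15 < gonadulin 0.35 — encoding the observed conservation ordering
(relaxin strongly conserved, gonadulin highly divergent) while keeping
within-family identity above the classifier's 0.5 threshold. Framework
cysteines, the signal, the arginine-rich segment and the GTV motif never
mutate; random filler avoids cysteine, so the framework is a sharp planted
signal.

**Gene structure.** Non-aIGF genes have two coding exons; the archetype aIGF
gene has four, with the alternative splice site in the middle of exon 3: the
long isoform keeps all of exon 3, the short isoform splices out its second
half (the arginine-rich segment), and the two isoform CDSs are
byte-identical elsewhere. Introns are GT..AG with random interiors;
transcripts carry no UTRs (expression tests construct UTRs explicitly where
needed). Reading-frame consistency of exon lengths is validated at spec
construction.

**Genomes.** Each cluster goes on its own scaffold with exact requested
intergenic distances between coding extents; decoy background is i.i.d.
40% GC (no repeat structure — simplicity over realism) and is
rejection-sampled, segment by segment and then genome-wide, so that no ORF
of ≥ 60 residues outside the planted genes matches the default framework.
Planted-gene recall and zero decoy hits are therefore true by construction
*of the generator*, and the tests verify that the detector agrees.

**Reads.** Spots choose a transcript multinomially by abundance weight and a
uniform start; paired spots emit opposite-strand mates across a configurable
insert; substitution errors are applied per base. There is no fragment-length
model, no quality model, no contamination — passing tests demonstrate
correctness of the arithmetic and algorithms on clean data, not robustness
to real library artifacts. `tile_spots()` provides deterministic even
coverage (starts every `step` nt, final window always included) for
full-reconstruction checks, where uniform random starts would leave the
extreme transcript ends uncovered with non-trivial probability.

**Worked-example inputs.** The package ships one small real table — a
published survey of gonadulin RPM across arthropod tissues — used for the
queen-ovary fold-change contrast (308-fold). The queen-vs-worker/male larva
contrast, whose underlying per-archive values are not available to this
package, is instead computed end-to-end on generator output with a planted
25-fold gonadulin abundance contrast, a value chosen once as consistent with
the published "at least 15-fold" statement; the pipeline must recover a
ratio ≥ 15 through the counting machinery, so the check exercises the
computation, not the plant.

## Problem sizes and numerical choices

Validation runs use sizes chosen for a single CPU: the planted-recovery
genome is 5 clusters (20 mRNAs) over ~1.2 Mb; the mining check rebuilds a
900-nt transcript from a 60-nt seed at ~30× tiling coverage; isoform truth
checks use 400–500 spots; NJ exactness uses up to 200 random trees of ≤ 12
taxa; similarity trees use 9 sequences × 100 bootstrap replicates. All
randomness flows through explicit integer seeds (`with_seed` restores the
caller's RNG state, so package functions never perturb a session's
randomness). Ties are broken lexicographically everywhere (framework
positions, assembly merges, NJ pairs, classification) so equal inputs give
byte-identical outputs.

Two numerical details deserve note. First, the isoform truth oracle in the
tests extends the isoform-common region past the splice junction by the
measured length of coincidental base agreement between the alternative
segment and the downstream exon — a read can legitimately match both
isoforms through a k-mer that straddles the junction by a base or two.
Second, `best_overlap`-style verification always rechecks anchored
candidates by full substring comparison, so hash or anchor collisions cannot
create false merges.

## Known limitations

* The signal-peptide heuristic is a fixed rule, not a trained predictor;
  its cleavage positions should not be over-interpreted.
* Similarity trees make no phylogenetic claims; supports quantify grouping
  stability only.
* The assembler has no splice-graph handling: alternative isoforms may
  assemble into two contigs, and isoform questions are handled downstream by
  the expression module, by design.
* The generator's decoy model (i.i.d., no repeats) understates the false
  positive opportunities of real genomes; the zero-false-positive result is
  a statement about the detector's specificity on that model.
* Expression counting is exact-match based; at realistic sequencing error
  rates the 32-nt criterion undercounts, and no error-aware correction is
  provided (the validated regime is error-free simulation).
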