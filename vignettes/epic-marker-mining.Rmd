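---
title: "Mining exon-primed intron-crossing markers from genome comparisons"
author: "epicmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining exon-primed intron-crossing markers from genome comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicmine)
```

## The problem

Multilocus studies of closely related species and populations need nuclear
markers that (i) amplify across a wide taxonomic range with one primer
pair, (ii) are single-copy so orthology is unambiguous, and (iii) carry
enough variation to be informative at shallow divergences. Exon-primed
intron-crossing (EPIC) markers satisfy all three: primers sit in coding
exons, which evolve slowly and provide near-universal priming sites, while
the amplicon spans the intervening intron, which evolves quickly and
supplies the variation. The scarcity of catalogued EPIC loci — especially
for teleost fishes, where several well-annotated genomes exist — is the gap
this package addresses: given one annotated *query* genome and one or more
*reference* genomes, it discovers introns flanked by single-copy, conserved
coding segments and reports them as a marker catalogue ready for primer
design (primer picking itself is deliberately out of scope).

## The screen

The pipeline (`run_pipeline()`) applies five filters in sequence:

1. **Large coding segments.** Each annotated CDS feature is one segment
   (per-segment, not per-transcript, granularity; for multi-transcript
   genes the longest-CDS transcript is used). Segments shorter than
   `min_cds_len` (default 100 bp, boundary inclusive) are dropped — shorter
   exons leave no room for a primer.
2. **Single-copy filter.** All surviving segments are aligned all-vs-all
   with the local aligner. A segment is discarded when some *other*
   sequence covers more than 20% of it at more than 40% identity (both
   strict inequalities). Multi-copy exons would amplify paralogous mixtures.
3. **Conservation mapping.** Each flanking exon of each remaining intron is
   mapped onto every reference genome by annotation-free local alignment
   (both strands of every chromosome). Annotation-free mapping is the
   deliberate default so that low-quality, unannotated assemblies can serve
   as references; the per-reference intron length is inferred as the gap
   between the two flanking-hit intervals, and a reference whose flank hits
   land on different chromosomes or strands counts as unmapped.
4. **Intron-size screen.** The intron must be at most `max_intron_len`
   (default 1,000 bp) in *at least one* of the compared species (query
   included) — short enough somewhere to PCR-amplify and sequence through.
5. **Identity tier.** The mean flanking-exon identity — averaged
   query-anchored over the references, and over the two flanks within each
   reference — must reach `min_mean_identity`. The tiers 0.65 / 0.80 / 0.85
   trade catalogue size against primer universality; 0.85 is the default
   because in practice primers work reliably above ~0.80. The mean is
   rounded to 2 decimals before the comparison, so "larger than 85%" admits
   a computed 0.849 ≈ 0.85; this inclusive reading is applied consistently.

Qualifying introns of the same gene that lie within `merge_window`
(default 1,000 bp) of each other — transitively chained — are reported as a
single marker spanning their union: one primer pair would amplify the whole
region anyway. Loci are named from the last five digits of the gene
identifier plus `E` and the index of the first merged intron's upstream
exon in chromosomal order (`59107E2` = the marker at the second exon
junction of gene …59107).

Two scoring choices depart from common alignment defaults, and both are
essential to the screen's behaviour:

* **Mismatch −1 instead of −3.** With the conventional −3 penalty, a local
  alignment of two orthologous exons breaks at short diverged patches and
  the conservation estimate fragments. The mild penalty lets alignments
  extend across occasional low-identity stretches, so identity is measured
  over the whole exon. Softening the penalty can never lower an optimal
  local score (a property the test suite asserts).
* **Identity and coverage conventions.** Identity is identical columns over
  *all* aligned columns, gap columns included; coverage is aligned
  (non-gap) query bases over the full query length. These match the
  conventions of BLAST-style tools, whose role the built-in engine takes.

## The alignment engine

`local_align()` is an exact affine-gap Smith–Waterman (Gotoh) in C++:
match +1, mismatch −1, a gap run of length *L* costs
`gap_open + L · gap_extend` (defaults 5 and 2, the classic nucleotide-BLAST
values, configurable via `scoring_scheme()`). `N` never counts as a match —
not even against another `N` — and is charged the mismatch penalty. A score
of 0 (no positive-scoring substring pair) yields an empty alignment, not an
error. Among co-optimal alignments the engine deterministically reports the
one ending earliest in the dynamic-programming matrix (query coordinate
first, then subject), with traceback preferring substitution columns over
gaps; co-optimal *scores*, which is what every filter consumes, are
unaffected by this tie-break.

Genome-scale mapping (`map_to_reference()`) does not run the full matrix
against whole chromosomes. It seeds with exact 12-mers sampled along the
query, merges the seeded neighbourhoods into windows, and runs the exact
engine inside each window; when no seed fires anywhere it falls back to an
exhaustive tiled scan (tiles overlap by three query lengths, so an optimal
local hit cannot straddle undetected). The seeded path is tested against
the exhaustive scan. The optional qualifying-hit floor
(`min_identity_floor`) requires *both* identity and query coverage to reach
the floor: any two sequences share some short, identity-rich local
alignment, so a bare identity threshold cannot distinguish a real homolog
from noise, whereas demanding that most of the segment aligns at that
identity reproduces the "no hit" outcome a heuristic search engine would
give. The all-vs-all self-search uses a score floor of 40 in the same
spirit: chance local alignments between unrelated coding segments of a few
hundred bp stay well below it under +1/−1 scoring, while any paralog hit
able to trip the 20%-coverage/40%-identity copy criterion clears it
comfortably.

## Amplifiability statistics

The validation side of the package works from a taxa × loci
presence/absence matrix (1/0/NA for amplified/failed/untested; the packaged
`teleost_panel_path()` matrix records the wet-lab test of 12 teleost EPIC
markers in 9 species). `success_rate()` and `taxa_amplified()` summarise
columns; `amplifiability_similarity()` (alias `da()`) compares two taxa as
shared markers over markers amplified in either — 0 means no shared
markers, 1 all shared; an empty union is reported as an error, not as 0.
`p_distance()` is the uncorrected proportion of differing sites with
pairwise deletion of gap/ambiguity sites (complete deletion available in
`p_distance_matrix()`), and `pearson_cor()` pairs the product-moment
coefficient with the exact two-sided t-transform p-value.
`intron_vs_distance()` and `amplifiability_vs_distance()` assemble the
pair-level scatter data connecting genetic distance with intron-size
differences and with shared amplifiability — the relationships that predict
how far a marker panel transfers across taxa. Reproducing the original
panel's correlation *values* would require the underlying GenBank/Ensembl
sequences; the operations themselves are validated by construction
(exact ±1 on linear inputs, formula-oracle equivalence) and on simulated
panels.

## The simulator and what passing tests mean

`simulate_genome_set()` generates the statistical structure the pipeline
assumes, with known ground truth: ancestral genes with exon/intron
architecture; per-species copies mutated independently from the ancestor
(a star phylogeny; independent per-site substitution to a uniformly chosen
different base; no rate heterogeneity); introns additionally perturbed by
geometric-length indels so intron sizes diverge across species; annotated
paralog copies planted in the query at a controlled identity (dispersed to
the other chromosome by default, or tandem); references emitted without
annotation to exercise the annotation-free mapping path. Defaults — 5
species, exons 120–300 bp, introns 200–900 bp, exon substitution 0.05 and
intron substitution 0.15 per lineage (realized query-vs-reference exon
identity ≈ 0.90, around the catalogue's strictest tier), intron indel rate
0.02 with mean length 4, duplicates at 0.95 identity — describe a
moderately diverged genome panel of the kind the screen targets. The truth
table records per-junction realized intron lengths and exon identities, and
`truth_qualifies()` re-derives marker status from those numbers alone, so
pipeline recovery is checked against an account of the data that never
touches the alignment code.

What the simulator does *not* model: rate heterogeneity along sequences,
codon structure and selection, splice-site motifs, exon indels, repeats and
low-complexity sequence, assembly gaps, and phylogenetic structure among
the references (all lineages are independent). Perfect recovery on
simulations therefore demonstrates the pipeline's logic — filters, mapping,
merging, naming — not its robustness to every feature of real genomes;
repeat-rich real assemblies will, for instance, stress the single-copy
filter in ways the simulator does not.

## Numerical and design choices

* **Coordinates.** 1-based inclusive everywhere inside the package (the
  R/Bioconductor convention of IRanges and Biostrings), which is also the
  GFF3 convention on input and the catalogue convention on output; BED
  export converts to 0-based half-open as that standard requires.
* **"Marker start".** Reported as the chromosomal start of the upstream
  flanking exon region by default; `marker_start_convention = "intron"`
  switches to the first intron's start. Either reading is defensible, so it
  is a parameter rather than a constant.
* **Consecutive exons.** A junction is screened only when its two flanking
  segments are consecutive in the gene and *both* survive the size and
  single-copy filters; junctions are not re-bridged across a filtered
  segment, since the would-be "intron" would contain coding sequence.
* **Merged markers.** Merged mean identity is the mean over constituent
  junctions; per-species intron lengths are summed over constituents and
  reported as NA when any constituent lacks that species.
* **Query-anchored averaging.** "Mean identity among the species" is
  computed query-vs-each-reference, never reference-vs-reference: the
  pipeline is query-driven and makes no reference–reference alignments.
* **Degenerate inputs.** Annotation-free genomes yield an empty gene list;
  single-exon genes yield no junctions; abutting CDS segments produce a
  warning and no intron; an empty candidate set produces a header-only
  catalogue and a successful exit.
* **Problem sizes.** The bundled tests and the acceptance script run on
  simulated sets of 5–20 genes across up to 5 species (tens of kilobases
  per genome) — small enough to verify every stage exactly, large enough
  to exercise seeding, duplication and merging. Genome-scale runs are a
  matter of wall-clock time, not of different code paths.

## Known limitations

* The intron-size screen uses hit-gap inference on references; a reference
  whose two flank hits embrace an unrelated insertion (or a misassembly)
  reports that artifactual length.
* Best-hit mapping without a reciprocal check can pair a query exon with a
  paralogous region of a reference when the true ortholog is missing from
  the assembly; the identity tier catches most but not all such cases.
* The merge rule reports one `Marker start` for a merged multi-intron
  region; downstream users wanting per-intron anatomy should consult the
  candidate table before merging.
* Exhaustive-scan fallback is quadratic in chromosome length and intended
  for small references; very large genomes should rely on the seeded path.
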