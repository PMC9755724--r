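---
title: "Exon-resolved conservation analysis of multi-exon protein families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exon-resolved conservation analysis of multi-exon protein families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonevo)
```

# The problem

Multi-exon neuronal proteins such as tau (the MAPT gene product) evolve very
unevenly across their exons: the microtubule-binding domain (MTBD, exons
9–13) is strongly conserved from fish to human, the N-terminal projection
exons 1–4 less so, and the large "4a" exon that defines the
high-molecular-weight Big tau isoform barely at all — its *size* (roughly
250 aa, or ~355 aa for the longer 4a-L variant) is far better conserved than
its sequence. Asking region-by-region questions therefore requires extracting
exon-defined regions from annotated proteins, aligning them pairwise across
species, and summarizing identity in a way that is comparable across regions
of different lengths. This package implements that workflow end to end, plus
a generative model of the evolutionary scenario (lineage-specific
*exonization*, the de-novo recruitment of intronic sequence into a new exon)
so every stage can be validated against known ground truth without any
database access.

# Coordinates and data model

All coordinates are 0-based, half-open, **on the protein** (amino-acid)
sequence; every region size is in aa. Proteins are plain data frames
(`record_id`, `species_label`, `residues`, `source_accession`), exon maps are
plain data frames (`record_id`, `exon_label`, `start`, `end`) validated to be
sorted, non-overlapping and uniquely labeled per record. Exon labels are
opaque tokens — `"4a"`, `"4a-L"`, `"6c"` need no special parsing; ordering
comes from coordinates. Unannotated inter-exon residues are permitted
(validation reports them as warnings, not errors), because exon assignment is
genuinely uncertain in distant lineages such as jawless fishes.

# Alignment conventions

`align_global()` is a three-state (Gotoh) affine-gap Needleman–Wunsch
aligner, written in C++ for speed. Conventions, chosen to reproduce the
published defaults of the classical EMBOSS global aligner:

* **Scoring**: BLOSUM62 by default (`load_scoring_scheme()` also exposes the
  other BLOSUM/PAM matrices shipped with Biostrings). `X` is scored by the
  matrix, no special-casing.
* **Gaps**: a gap of length $L$ costs $\mathrm{open} + (L-1)\cdot
  \mathrm{ext}$, defaults open 10, ext 0.5. Terminal gap runs are free unless
  `penalize_end_gaps = TRUE`.
* **Statistics** (`alignment_stats()`): the denominator of identity,
  similarity and gap percentages is the **total number of alignment
  columns, gap columns included**. This matters: MSA tools often report
  identity over matched columns only, which inflates percentages for gappy
  pairs. A column is *similar* when identical or when its substitution score
  is positive. `max_window_identity` is the highest fraction of identical
  columns in any sliding window (default 30 columns), the basis of the
  "scattered vs contiguous" significance call below.
* **Determinism**: traceback ties prefer diagonal, then gap-in-second, then
  gap-in-first sequence, so every statistic is bit-reproducible. Identity is
  symmetric in the inputs to within 0.5 points (ties can resolve
  differently); scores are exactly symmetric.

Correctness is checked two independent ways: exhaustive enumeration of all
global alignments on short random pairs (exact score equality, both end-gap
modes), and score agreement with `Biostrings::pairwiseAlignment` (whose
`gapOpening = 9.5, gapExtension = 0.5` reproduces this gap convention).

# Regions, big-exon discovery and classification

`extract_region()` concatenates labeled intervals in map order;
`region_homology_table()` and `identity_matrix()` then tabulate pairwise
region identities against a reference or all-vs-all. Identity matrices are
built from pairwise global alignments (not an MSA): each unordered pair is
aligned once and entered symmetrically, diagonal 100. Rows for regions a
species lacks are skipped, mirroring the blank cells of a printed homology
table.

`infer_big_exon()` finds an unannotated big exon by **flank anchoring**, the
computational analogue of the manual curation used for distant vertebrates:
align the full target against a fully annotated reference, project the
reference coordinates *end of exon 4* and *start of exon 5* through the
alignment, and take the target interval strictly between the projections.
The full-sequence alignment is used rather than mini-alignments of the
anchor exons alone, because short diverged exons align unstably on their
own. A reference position landing in a gap column projects to the nearest
target position toward the candidate interior — the call can only shrink,
never absorb flank residues. `anchor_confidence` reports the identity
fraction over the 30 columns flanking each projection.

Candidates are classified by length (`classify_exon4a()`): below 150 aa the
call is `none` (no big exon), 150–334 aa is `4a`, 335 aa and above is
`4a-L`. The bands are induced from the observed size ranges in the bundled
cross-species survey — 4a exons span 208–320 aa, 4a-L exons 347–400 aa —
and 335 splits the gap between the two ranges; both edges are arguments, not
constants. 4a-L is treated as a longer variant of the same locus (in human
it extends 4a by 104 aa), so the pipeline never aligns a 4a region against a
4a-L sub-region.

# Significance and conservation ratios

A homology signal is called **significant** (`classify_homology()`) when
overall identity is at least 20% *and* the best 30-column window reaches
40% identity. The first threshold is the conventional noise floor for
global protein alignments (random 250 aa pairs typically land below 20%
under these conventions — verified by simulation in the test suite); the
second operationalizes the qualitative notion of matches "scattered without
distinct areas of contiguous identity": genuinely homologous regions retain
at least one locally conserved stretch, while scatter at the noise floor
does not. Both knobs are exposed as arguments; the call is monotone in both
statistics.

`conservation_ratio()` expresses one region's mean identity relative to
another's (`100 × mean(numerator) / mean(denominator)`), reporting both the
unrounded value and the nearest integer, since such ratios are
conventionally quoted as whole percentages. On the bundled survey the
big-exon identities of the eight non-mammal vertebrates relative to their
MTBD identities give 26.53 → **27%**, the two extremes of the conservation
spectrum.

# Trees

`identity_to_distance()` uses the plain complement $d = 100 -
\mathrm{identity}$ (symmetrized; zero diagonal). No Poisson/Kimura-type
correction is applied: the trees are descriptive overviews of identity
structure, and correction formulas diverge exactly where the big exon lives,
near the noise floor. `nj_tree()` runs standard Saitou–Nei neighbor joining
(via ape); on additive matrices it provably recovers the generating topology
and branch lengths, which the tests verify on random 5–8-taxon trees.
Negative branch lengths — an NJ artifact on non-additive input — are clamped
to zero with a message. `write_newick()` writes 6-decimal branch lengths and
single-quotes labels containing whitespace or Newick metacharacters (the
serializer is local because ape's writer rewrites such labels).

# The synthetic family generator

`simulate_family()` evolves a multi-exon protein along a user-supplied
phylogeny:

* **Architecture**: an ordered list of regions with lengths and per-site
  substitution rates. The default preset architecture (170 aa N-terminal-like
  at a medium rate, 100 aa mid region, 250 aa MTBD-like at a low rate,
  optional ~251 aa insert at a high rate) approximates the human protein.
* **Substitutions**: along a branch of length $t$, each site of a region
  with rate $r$ is redrawn with probability $1 - e^{-rt}$, uniformly over
  the 20 residues. Redrawing over all 20 (rather than the 19 others) makes
  the process a 20-state Jukes–Cantor chain in which multiple hits can be
  silent, and gives the exact closed form used for calibration: two leaves
  separated by total path $T$ agree at a site with probability
  $\tfrac{1}{20} + \tfrac{19}{20}e^{-rT}$. A uniform model is appropriate
  because percent identity — the only statistic the pipeline consumes — is
  insensitive to residue composition; a BLOSUM-conditioned process would add
  realism the statistics cannot see while destroying the closed form.
* **Indels**: Poisson events (rate per site per unit branch length), equally
  insertions/deletions, geometric lengths, uniform positions, never
  straddling a region boundary (straddlers are resampled). This keeps
  per-region ground truth well defined; real indels do cross exon
  boundaries, which is one reason simulated families are cleaner than real
  ones.
* **Exonization**: an event names a branch (by child node label), a length
  distribution and an insertion point; the child node acquires a fresh
  **uniform-composition** exon inherited by all descendants. Fresh uniform
  composition is the point: independently exonized inserts in different
  lineages share no homology beyond the alignment noise floor, which is
  exactly the observed signature of independent exonization in real data.
  Events apply at the child end of the branch (the insert does not evolve
  along the branch that creates it).
* **Determinism**: identical config + seed give byte-identical FASTA, exon
  maps and truth records.

What the generator does *not* emulate: codon-level evolution and selection,
composition bias, rate variation within regions, splice-site or
transposable-element sequence structure, and annotation error. Passing
recovery tests therefore demonstrate the pipeline's correctness under the
stated model, not robustness to every pathology of real annotations.

## Presets and the recovery experiment

`make_preset()` bundles four study designs; sizes and rates are
package choices made once. `"recovery_3rate"` is the parameter-recovery
design: six leaves, three regions at well-separated rates (0.01 MTBD-like,
0.05 N-terminal-like, 0.30 insert), one exonization of a ~251 aa exon on an
internal branch covering four leaves, no indels. The mid region keeps the
low rate so the right anchor flank stays stable. `run_recovery_experiment()`
anchors detection on an annotated **carrier** leaf — as the real analysis
anchors on the annotated human Big tau isoform — which makes boundary
recovery exact in the no-indel design (carrier and reference inherit the
same-length insert, so their alignment is gap-free); insert-free leaves
exercise the long-gap case and provide specificity. The rate/divergence
Spearman correlation is computed over the three distinct-rate regions.
`"primate_4a"` (shallow tree, shared insert) keeps big-exon identities above
85; `"vertebrate_4a"` (deep tree, independent inserts per lineage, one
4a-L-sized) reproduces the qualitative gradient MTBD ≫ N-terminal ≫ big exon
with the big exon at the noise floor; `"jawless"` has no insert and only the
MTBD-like region retaining clear identity.

# Numerical choices and degenerate inputs

Empty sequences are errors for alignment; empty FASTA files parse to empty
collections. Alignments shorter than the statistics window use one window of
the full length. `conservation_ratio()` refuses empty lists and zero
denominators. Negative candidate lengths cannot occur (the projection
clamps); negative classification lengths are errors. Identity matrices
require two records with the region; NJ requires three leaves. In
`run_report()`, any stage failure removes partial outputs and rethrows with
the stage name; `report.json` is byte-stable across reruns except for its
timestamp.

# Problem sizes used by the tests and the acceptance script

Chosen to give tight checks at interactive runtimes: 200 random pairs of
length ≤ 6 against the brute-force enumeration oracle (plus 60 in the unit
tests covering both end-gap modes); 50 random additive 5–8-taxon matrices
for NJ; 20 replicate seeds of the recovery design for parameter recovery;
5000-site regions (pooled over 5 replicate pairs in the acceptance script)
for the closed-form calibration, which puts the Monte-Carlo standard error
near 0.3 identity points per region. The whole suite runs in well under a
minute.

# Known limitations

* Identity matrices come from all-vs-all pairwise alignments; MSA-based
  matrices differ by small amounts (the two agree to within a few points in
  practice), so cross-tool comparisons should allow that tolerance.
* The "scattered" significance criterion (40% in a 30-column window) is an
  operationalization of a qualitative judgment; different window settings
  shift borderline calls.
* Distances are uncorrected identity complements; the trees are descriptive,
  not dated phylogenies, and long branches are compressed relative to any
  corrected estimate.
* Big-exon boundary calls wobble by tens of residues at deep divergence when
  the reference lacks a homologous insert; calls remain class-correct because
  classification depends on length bands, not exact boundaries.
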