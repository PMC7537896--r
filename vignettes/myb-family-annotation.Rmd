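---
title: "Annotating a plant MYB transcription factor family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating a plant MYB transcription factor family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mybkit)
```

# Scope

`mybkit` implements the downstream half of a genome-wide gene-family survey
of the kind routinely performed for plant R2R3-MYB transcription factors:
given candidate protein sequences, gene models (GFF3) and an RNA-Seq count
or FPKM matrix, it

1. detects tandem MYB repeats and classifies domain architectures
   (1R / R2R3 / 3R / 4R),
2. scans for the bHLH-interaction consensus motif that marks candidate
   members of MYB–bHLH–WD40 (MBW) complexes,
3. places the family on a neighbor-joining tree with bootstrap supports
   and transfers clade labels from annotated reference domains, flagging
   lineage-specific groups,
4. computes exon-structure and chromosomal-distribution statistics, and
5. classifies per-gene expression breadth across organ groups.

The upstream stages of a real survey — homology search against a genome
assembly, read mapping and counting — are deliberately out of scope: the
package consumes their standard outputs. A packaged catalog of the 294
annotated *Musa acuminata* (DH-Pahang v2) MYB genes and its 17-sample
FPKM table serve as a reference data set, and a synthetic-data generator
with a planted-truth manifest makes every stage testable without
downloads.

# The repeat model

A MYB repeat is an imperfect ~50–53 residue module folding into three
alpha-helices, with three regularly spaced tryptophan (or hydrophobic)
residues forming the hydrophobic core of a helix–turn–helix. The scanner
models one repeat as a *profile*: a consensus sequence, a matrix of
per-position residue scores, and the three tryptophan anchor positions.

Detection runs Smith–Waterman local alignment of the protein against the
profile under the position weights and a linear gap penalty; the
best-scoring hit is recorded, its residues masked, and the search repeats
(greedy masking), so hits are non-overlapping by construction. A hit must
span at least `min_len` residues (default 45) to count as an intact
repeat. Architectures map directly from the hit count: 0 → `none`,
1 → `1R`, 2 → `R2R3`, 3 → `3R`, ≥4 → `4R`; family surveys retain genes
with two or more repeats, and CDC5-like proteins — atypical two-repeat
MYB-related genes recognisable only by orthology — are supplied by
annotation, never called from sequence.

Key parameters:

* **Position weights** — default BLOSUM62 rows of the consensus residues
  (dimensionless log-odds units), so profile alignment scores behave like
  BLAST-family protein scores. Any matrix of the same shape may be
  supplied.
* **`min_score`** — default half the profile self-score. The
  threshold is intentionally permissive: repeats are imperfect, and the
  family decision (≥ 2 repeats) tolerates borderline single hits. On
  uniform-random background the probability of a half-self-score local
  match is negligible, which the precision metrics on synthetic bundles
  confirm.
* **`gap_penalty`** — default −8 per gapped residue, on the BLOSUM62
  integer scale.
* **Tryptophan anchors** are *reported*, not required: each hit carries
  the count of anchor positions holding W or another hydrophobic residue
  (W F Y L I V M A), for downstream filtering. Requiring them would
  discard genuine repeats in which one core position diverged.

The default consensus shipped with the package
(`default_myb_profile()`) is a package-authored 52-residue plant-style
R2R3 repeat with anchors at positions 6/26/46. It is synthetic: a real
survey should substitute its own curated consensus, and nothing in the
package's checks depends on the default's exact content.

# The bHLH-interaction motif

The motif scan is exact, not statistical: every 20-residue window is
tested against the positional pattern `[D/E]Lx2[R/K]x3Lx6Lx3R` (six
constrained positions; `x` matches anything including `X`, while `X`
never satisfies a constrained position). Overlapping matches are all
reported; downstream only presence/absence per gene is used. The whole
protein is scanned rather than only the R3 repeat — the motif's position
relative to detected repeats is available to the user, but no positional
filter is applied, because imposing one would silently depend on repeat
coordinates that are themselves predictions.

# Phylogenetic classification

The classification stage answers one question: *which annotated clade
does each query domain belong to?* For that purpose the package uses
distance methods throughout — pairwise global alignment (match 2,
mismatch −1, gap −2; deterministic traceback with tie order
diagonal > up > left), p-distances (mismatched columns over gap-free
compared columns; an optional Poisson correction `-ln(1-p)` is available
by flag), Saitou–Nei neighbor-joining, and a column bootstrap. Full
maximum-likelihood inference is a deliberate non-goal: labels are
transferred from references by tree position, so a monotone distance and
supported splits suffice, at a small fraction of the cost. Clade
identities are therefore meaningful only relative to the supplied
reference labels, never as absolute clade numbers.

Numerical and algorithmic choices:

* **Master alignment.** Column bootstrapping needs one columnar
  alignment. The package builds it center-star style: the sequence with
  the highest summed pairwise score to all others anchors the columns,
  and pairwise center insertions are pooled (shorter insertions
  right-padded). Equal-length input — the common case for extracted
  domains of the same repeat count, or user-supplied pre-aligned FASTA —
  is used as columns directly. Center-star is adequate for the
  well-conserved repeat region; for distant or heavily gapped sets a
  dedicated aligner's output should be supplied pre-aligned.
* **Neighbor-joining determinism.** Ties in the Q criterion are broken
  by the lexicographically smallest pair of representative leaf ids;
  negative branch-length estimates are clamped to zero and counted in
  the `"clamped"` attribute.
* **Bootstrap.** `B` column resamples (default 1000) rebuild the NJ tree;
  the majority-rule (>50%) consensus and the full-data tree are both
  annotated with percent supports. A single integer seed drives the one
  resampling stream, so runs are reproducible bit for bit.
* **Clade assignment** works on splits, not on the stored rooting: for
  each query the smallest well-supported side containing it and at least
  one reference votes by majority of reference labels; size ties are
  broken by mean patristic distance to the side's references, and tied
  votes return `"unresolved"`. Reference-free groups of two or more
  tips become `lineage-specific:k` when their context mixes clades, or
  when a single-clade context lies further away than
  `ls_distance_factor` (default 2) times that clade's own reference
  spread — the signature of a long-stemmed sister lineage rather than a
  clade member. The defaults were chosen from the geometry of the
  synthetic families (within-clade divergence well below between-clade
  divergence); on flat trees with no such separation the distinction is
  not identifiable, and assignments degrade to `"unresolved"` rather
  than to confident errors.
* **Domain extraction convention.** For multi-repeat proteins the
  "domain" entering the tree is the concatenation of detected repeat
  hits, for 3R/4R proteins included. This is a convention, flagged here:
  alternatives (R2R3-only spans, full-length proteins) change distances
  for the atypical classes.

# Gene structure and the catalog

`parse_gff()` (an rtracklayer import behind a stable interface) collapses
the gene/mRNA/exon/CDS hierarchy to one model per gene. Exon counts come
from the *primary transcript*, defined as the transcript with the largest
summed exon length; `count = "cds"` switches to CDS segments — "coding
exons" in published tables is ambiguous between the two, so both modes
exist, and on the packaged catalog the exon-feature mode reproduces the
published histogram. Coordinates are 1-based inclusive throughout, exons
always in ascending genomic order regardless of strand.

Catalog statistics follow the conventions of printed survey tables:
percentages round half-up to one decimal (`round_half_up()`), family
shares to two significant figures, and entries sort by pseudochromosome
Ma01…Ma11 with the unplaced Ma00 bin last, then by start coordinate.

# Expression breadth

FPKM is computed as `counts * 1e9 / (length * total)` per gene and
sample. A gene is *expressed* in a sample when its value exceeds a
threshold whose default is 0 — any signal counts. Surveys rarely state
their cutoff, and on integer-rounded published tables a zero threshold
reproduces the qualitative row behaviour; `--min-fpkm`-style overrides
are a single argument away. Organ-group breadth (six groups over the
17-sample banana design: embryogenic, seedling, root, leaf ×4 stages,
pulp ×5, peel ×5) declares an organ expressed when any member sample is,
and classifies genes as `all_samples`, `none`, or `some`, with
organ-exclusive genes flagged. Note the asymmetry this creates for
multi-sample organs: a per-organ count (any member sample) is
systematically larger than a per-sample count; the package reports
group-level breadth and leaves per-sample tallies to the caller, both
being one comparison on the matrix. Paralog profiles are compared by
Pearson correlation of `log2(FPKM + 1)` (pseudocount bounds the
influence of zeros) plus the Jaccard overlap of expressed-organ sets.

# The synthetic generator

`generate_family()` produces a complete input bundle — proteins, GFF3,
counts/lengths/totals, labelled reference domains — together with a
manifest of the planted truth, under a single master seed with named
substreams (`sequence`, `structure`, `expression`) so each component can
be regenerated independently.

Defaults mirror the published banana family: 285 R2R3 + 6 3R + 2 4R
retained genes (plus 50 + 50 background proteins without a multi-repeat
domain), the published exon-count distribution with its 3-exon mode, an
unplaced fraction of 3/294, roughly one retained gene in ten carrying a
bHLH motif, and breadth-class fractions matching the published
none/at-least-one counts. Planted repeats are copies of a clade ancestor
(itself `clade_divergence = 0.15` from the profile consensus) mutated at
`mutation_rate = 0.05` per residue — values chosen so that within-clade
distances sit well below between-clade distances, the regime in which
clade classification is identifiable at all. One of the eight simulated
clades carries no references, emulating the lineage-specific clades real
surveys report. Expression values are log-normal (meanlog 2, sdlog 1, in
FPKM units) over planted organ sets, back-converted to integer counts so
that the FPKM round trip is exact at threshold 0.

What the generator does *not* emulate — and what passing tests on it
therefore cannot show — includes: compositional bias and low-complexity
regions of real proteomes (linkers are uniform over the 20 residues),
insertions/deletions inside repeats, correlated expression noise across
samples, unbalanced library sizes, alternative splicing, and any
disagreement between protein length and the gene model. Results on real
data depend on the curated repeat consensus in a way no synthetic test
exercises.

# Problem sizes and runtime choices

The shipped checks run the scanner on bundles of ~200–400 proteins, the
topology-recovery property on 100 random additive matrices of 4–12 taxa,
bootstrap classification on ~65 queries against 27 references with
B = 50, and the motif oracle on 1000 random 500-residue sequences —
sizes chosen so the whole suite completes in about a minute while every
property is exercised at non-trivial scale. The same machinery runs
unchanged at survey scale (hundreds of domains, B = 1000); only the
bootstrap stage's cost grows appreciably, roughly linearly in B and
quadratically in the number of leaves per replicate.

# Known limitations

* The repeat scanner's greedy masking cannot represent overlapping
  repeat hypotheses; for MYB-like tandem arrays this is the desired
  geometry, but it is not a general repeat finder.
* HMM-based domain models, E-values and six-frame translation are out of
  scope; the scanner operates on candidate *protein* sequences.
* Center-star alignment degrades for sets with long, inconsistent
  insertions (e.g. mixing 2R and 4R domains); supply a pre-aligned FASTA
  in such cases.
* Clade labels transfer only as well as the reference set covers the
  tree; sparse or mislabelled references surface as `"unresolved"` or as
  spurious lineage-specific groups.
* Expression breadth on integer-rounded published tables is not
  identical to breadth on the unrounded values the original analyses
  used; near-threshold counts (notably "expressed in all samples")
  differ by a few genes.
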