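---
title: "Methods: annotating and classifying a gustatory receptor repertoire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and classifying a gustatory receptor repertoire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grannot)
```

`grannot` re-implements, as small composable functions, the workflow used to
characterise a large insect gustatory receptor (GR) family on genome
scaffolds. This vignette is the package's own account of the models and
procedures, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the design choices made where the design was
genuinely open.

## Coordinate conventions and gene models

All interval arithmetic inside the package uses 0-based half-open
coordinates; GFF3's 1-based inclusive convention is converted exactly once,
at the I/O boundary (`read_gff3()`), which keeps exon/intron bookkeeping
free of ±1 corrections. A gene model stores its exons sorted by genomic
position, its CDS spliced in transcription order (minus-strand CDS is the
reverse complement of the concatenated exons), and its translation.

Translation follows the standard genetic code with two deliberate rules:

* codons containing `N` translate to `X` and **never** call a stop, so an
  ambiguous base can never create a pseudogene call;
* a trailing stop codon is trimmed from the protein, while internal stops
  are retained as `*` and set the `internal_stop` flag.

CDS phase fields are honored when present; an absent phase is assumed to be
0 with a logged warning, since a curated GFF3 without phases almost always
encodes phase-0 models.

## The translated homology screen

The discovery stage mimics a translated (protein-vs-genome) search:
scaffolds are translated in six frames (`six_frame_translate()`), and each
query is matched by exact-and-neighborhood word seeding on BLOSUM62 — a
seed is any query/subject word pair of length 3 scoring ≥ 11 — followed by
ungapped two-sided extension that abandons a direction when the running
score drops more than `x_drop = 20` below its maximum. Extensions never
cross a stop (`*`) in the translated frame. HSPs scoring ≥ 50 are reported,
and HSPs on one scaffold and strand merge into a candidate locus when their
genomic gaps are at most 10 kb — an intron-sized allowance.

Two scope decisions keep this stage honest and testable. First, extension
is ungapped only: candidate loci are refined downstream against the curated
GFF3, so the screen only needs to *find* loci, not produce final
alignments; ungapped scores are exactly re-summable from the matrix, which
the test suite exploits (every reported score is recomputed entry by entry,
and reported HSPs are checked to contain the best ungapped segment per
diagonal found by an exhaustive scan). Second, there are no E-values — raw
score thresholds are used, and all parameters are exposed, because no
published cutoffs exist for the original screen. Ambiguity codes in queries
(U/O/B/Z/J) map to `X`, which scores 0 against everything.

## Distances, the NJ tree, and subfamily assignment

Subfamily classification needs clade membership, not branch-length
fidelity. The package therefore uses distance-based neighbor joining rather
than a likelihood tree search: NJ is deterministic at desk scale and admits
an exact oracle — on any additive matrix the recovered tree must reproduce
every input distance as a path length, which the tests verify directly and
against a brute-force enumeration of all 5-taxon topologies fit by least
squares.

Distances come from a multiple alignment computed with MAFFT (single
thread, fixed input order, hence reproducible); the package's own global
pairwise aligner (Needleman–Wunsch via Biostrings, BLOSUM62, affine gaps)
backs the two-sequence `pairwise_distance()` entry point. Columns with a
gap (or `X`) in either sequence are excluded pairwise — the "partial
deletion" convention — and the distance is either the mismatch proportion
`p` or its Poisson correction `-ln(1 - p)`, capped (default 10) as `p`
saturates. Two fragments that occupy disjoint alignment regions (possible
when a pseudogene's stop-free segment meets a partial model) receive the
cap with a warning rather than failing the matrix.

The NJ implementation follows the canonical Saitou–Nei algorithm with the
Studier–Keppler Q criterion and two documented refinements: ties in Q are
broken by the lexicographically smallest pair of cluster labels (a cluster
is labelled by its smallest member), making the tree a pure function of the
matrix; and a negative branch length is clamped to zero with the deficit
moved to its sister edge, preserving the pair distance. Pseudogenes enter
the tree as their longest stop-free translated segment.

Assignment walks from each gene's leaf toward the rest of the tree and
takes the subfamily of the first enclosing clade that contains an anchor,
by majority over the anchors in that clade; exact ties fall back to
lexicographic subfamily order and are flagged. The "walk" is implemented as
the parent chain on a midpoint-rooted view of the tree. This was a genuine
design choice: minimising over *all* unrooted bipartitions containing the
gene admits complement components — "everything except some anchor-free
subclade" — which can be smaller than the gene's true family clade yet
contain only foreign anchors; the rooted walk cannot produce such
components, and midpoint rooting places the root on the long inter-family
branch whenever the anchors separate families at all.

Bootstrap support resamples alignment columns with replacement, rebuilds
the NJ tree per replicate, and scores each original bipartition by the
percentage of replicates containing it. On synthetic repertoires the
within-family branching is star-like by construction (every gene is an
independent mutant of one ancestor), so within-family supports are low and
carry no signal; the family-separating edges are the informative ones and
reach 100 in the shipped workflow.

## Bitter receptor typing

The bitter clade is typed from gene structure and protein length:

| type | structure | length |
|------|-----------|--------|
| Type 1 | ≥ 2 exons | ~400 aa |
| Type 2 | intronless | > 400 aa |
| Type 3 | intronless | 200–350 aa (sharp bound < 360) |

The sharp thresholds (> 400, < 360) are taken from the scheme's explicit
figures rather than its approximate ranges, and both are configurable.
Intronless lengths in [360, 400] or below 200 aa fall in ranges the scheme
leaves uncovered and are reported as `unknown` — the summary keeps an
explicit unknown column rather than forcing a nearest type. Pseudogenes
keep their structural measurements but are tallied in their own column
outside the typed counts, and partial models are never length-typed even
when their intron status is known, since a missing terminus biases length.
Consequently `type1 + type2 + type3 + unknown = bitter − pseudogenes`,
which the summary asserts. The published catalog shipped in
`inst/extdata/harm_gr_catalog.tsv` flags 13 partial models while the
summary's unknown column holds 7; the two bookkeeping quantities are
reported separately precisely because the mapping between them is not
fully specified in the source material.

## Tandem arrays

Arrays chain genes per scaffold while the gap between consecutive members
(`next start − previous end`) stays within `max_gap` (default 100 kb), and
are reported when they reach `min_array_size` (default 3) members. When a
type filter is applied, gaps are measured between consecutive genes *of
that type*, ignoring interleaved genes of other types — scaffolds that
interleave Type 1 and Type 3 genes still yield clean per-type arrays. Spans
(`last end − first start`) are reported per array so cluster geometry can
be checked against any published span regardless of the gap parameter;
whether a published "within 0.2 Mb" figure was a criterion or a measurement
is ambiguous, and the package treats it as a measured span.

## Expression presence/absence

Counts are normalised to RPKM — `count / (gene length in kb × library size
in millions)` — and a gene is called present in a library when its
abundance reaches a conservative cutoff, default 1.0 RPKM, echoed in every
output. The formula and cutoff are package choices: the original profiling
tool and its threshold are unpublished. Detection requires a single library
above cutoff because tissue libraries carry no biological replication, and
no between-library differential testing is offered for the same reason.
Lowering the cutoff can only add present calls; the tests assert this
monotonicity, and detection counts per library group plus per-gene breadth
(number of libraries with a call) are the summary outputs.

## Topology prediction

A single transparent predictor replaces external web tools: mean
Kyte–Doolittle hydropathy over a centered window (default 19, edges
truncated), runs of scores ≥ 1.6 merged across sub-threshold gaps shorter
than 4 and kept at ≥ 15 residues become TM segments. The N-terminus side
follows the positive-inside rule — the terminus-adjacent loop with more
K+R residues is intracellular (ties favour N) — and the C-terminus follows
by parity: an odd helix count places the termini on opposite membrane
sides, an even count on the same side. The parity law is asserted on every
output. A consensus operation over a parameter grid mirrors the common
practice of comparing several predictors: the median helix count (ties to
the lower value), segments from the first parameterization achieving it,
termini by majority with parity repair.

## The synthetic-data generator

The generator is first-class, tested code and defines the study conditions.
Its default composition is the characterised repertoire the package
emulates: 197 genes (3 CO2, 8 sugar, 2 GR43a-like; 31 Type 1, 13 Type 2,
129 Type 3; 4 pseudogenes; 7 partial models), a 38-gene Type 3 tandem
array, a 9-gene Type 2 array, and a scaffold interleaving 5 Type 1 with 9
Type 3 genes. Genes are built by mutating a seeded random ancestor protein
per subfamily at 10% divergence (anchors at 2%), back-translating with
uniform synonymous codons, and implanting the structure their type
prescribes (3–4 exons for Type 1, single exons otherwise; introns 60–400 bp
with GT..AG ends). Length bands keep a 10-residue guard margin away from
every classification threshold so type truth is unambiguous. Family members
share the ancestor's C-terminal region — length variation trims the
N-terminus — emulating the conserved C-terminal domain of this receptor
family; without that choice two same-family genes could share no aligned
columns at all. Array gaps are drawn from 2.5–4 kb, which places the
38-gene array's span near 0.15 Mb; other intergenic gaps are exponential
with mean 3 kb.

The default expression design emits 31 libraries — four developmental-stage
libraries, 14 larval-tissue and 13 adult-tissue libraries — with a fixed
detection truth of 84 distinct expressed genes: 12 detected in embryos, 4
in 3rd instar, 12 in 5th instar, 18 in pupae, 20 across larval tissues and
73 across adult tissues. (The emulated panel's own tissue arithmetic
slightly exceeds 31, so the larval-tissue group was fixed at 14 to keep the
library total at 31.) Expressed cells draw abundances 10–100× the cutoff
and counts are Poisson with mean `abundance × kb × million reads`, the
exact inverse of the RPKM normalisation, so presence recovery failures are
bounded by Poisson tails (≤ e^{-λ/3} per cell, negligible at these means);
silent cells are exactly zero.

Synthetic membrane proteins implant `k` 21-residue helices of I/V between
hydrophilic loops. Loop interiors and the six residues flanking each helix
are drawn from D/E/N/Q — all with Kyte–Doolittle value exactly −3.5 — and
helices from I/V (4.5/4.2), which makes recovery at the default parameters
an arithmetic identity rather than a sampling outcome: a 19-window with 13
helix residues scores at least (13·4.2 − 6·3.5)/19 ≈ 1.77 > 1.6, one with
12 scores at most (12·4.5 − 7·3.5)/19 ≈ 1.55 < 1.6, so each helix yields
exactly the 15-position run the segment filter requires. Interior loops are
at least 12 residues so adjacent helices can never merge under the default
merge gap; the distal part of a terminal loop is K/R-enriched on whichever
side the truth marks intracellular. Two limitations are deliberate: a
protein whose termini are both extracellular cannot be recovered
terminus-for-terminus by a positive-inside predictor (the helix count and
parity still are), and the *repertoire* generator implants no helices at
all — its proteins emulate family structure, not membrane architecture, so
repertoire-wide topology tables are expected to read 0 TMDs and the
topology stage is validated on the membrane-protein generator instead.

What passing tests on this synthetic data do show: coordinate and splicing
arithmetic, classification logic, array chaining, normalisation and
thresholding, tree construction and anchored assignment behave exactly as
specified under known truth. What they cannot show: performance on real
assemblies with fragmented gene models, alignment error, codon bias,
overdispersed counts, or genuinely ambiguous clade structure — real
divergence within this family is far deeper than the 10% the generator
uses, and a likelihood tree on a curated alignment remains the right tool
for publication-grade phylogenies.

## Problem sizes and determinism

The shipped workflow runs the full 197-gene genome (about 0.86 Mb over 17
scaffolds): MAFFT on 210 sequences, a 210-taxon NJ tree and the complete
typing/cluster/expression/topology chain complete in well under a minute,
and the test suite's larger property checks (ten 500-gene repertoires,
1000 membrane proteins) were sized to keep the whole suite around a
minute. Every stochastic step flows through a single integer seed
(`withr::with_seed`), reruns with an identical configuration are
byte-identical (asserted in the tests), and the pipeline writes a manifest
with every parameter and an MD5 checksum per output.

## Known limitations

* The homology screen is ungapped and statistics-free by design; it is a
  discovery stage, not an aligner.
* NJ on Poisson-corrected distances is a classification device; branch
  lengths and deep topology should not be over-interpreted.
* Midpoint rooting assumes the inter-family branch is the tree's longest
  path; pathological anchor sets could violate this.
* The expression module consumes counts; mapping and quantification are
  upstream concerns.
* Hydropathy-threshold topology prediction is deliberately simple; it
  reproduces helix counts on idealised sequences, not the output of
  HMM-based predictors on real ones.
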