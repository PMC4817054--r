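# grannot — annotation and classification of insect gustatory receptor repertoires

Insect gustatory receptors (GRs) sit at the interface between the taste
system and the environment, and polyphagous pest species carry dramatically
expanded GR families — in particular a large "bitter" receptor clade.
Characterising such a repertoire from a genome assembly is a stereotyped but
multi-stage job: find candidate loci by translated homology, build gene
models, place every gene in a subfamily against reference anchors, type the
bitter receptors by gene structure and length, map tandem gene arrays on
scaffolds, profile expression across tissue libraries, and predict membrane
topology. `grannot` implements that pipeline as small, testable R functions,
and pairs it with a synthetic-data generator that produces fully
ground-truthed genomes, count matrices and membrane proteins, so every stage
can be validated end to end without access to unpublished assemblies.

The package is aimed at researchers annotating chemoreceptor (or other
large, tandemly duplicated) gene families, and at anyone who wants a
transparent, dependency-light reimplementation of the classic
screen–classify–type workflow.

## The methods in brief

* **Homology screen** — scaffolds are translated in all six frames and
  searched with reference GR proteins using BLOSUM62 word seeding
  (word size 3, seed threshold 11), ungapped two-sided X-drop extension and
  a raw score cutoff; HSPs on one scaffold and strand merge into candidate
  loci when their genomic gaps stay within an intron-sized bound.
* **Subfamily assignment** — gene proteins and anchor proteins are multiply
  aligned (MAFFT), pairwise distances are computed with pairwise deletion of
  gap columns under `p` or Poisson-corrected (`-ln(1 - p)`) models, a
  neighbor-joining tree is built (Saitou–Nei Q criterion, deterministic
  tie-breaks, non-negative branch lengths), and each gene takes the
  subfamily of the first anchored clade on its walk toward the root
  (CO2, sugar, GR43a-like or bitter). Column-bootstrap support is available.
* **Bitter typing** — Type 1: intron-containing; Type 2: intronless,
  > 400 aa; Type 3: intronless, 200–350 aa (< 360 aa). Pseudogenes
  (internal stop codon) are counted separately; partial models (missing
  start Met or terminal stop) stay untyped.
* **Tandem arrays** — maximal same-type gene chains per scaffold under a
  configurable gap bound, reported with size and span.
* **Expression** — counts are normalised to RPKM
  (`reads / (kb × million mapped reads)`) and a conservative cutoff
  (default 1.0) gives presence/absence calls and per-group detection counts.
* **Topology** — Kyte–Doolittle sliding-window hydropathy (window 19,
  threshold 1.6, minimum helix 15), positive-inside termini assignment and
  the parity rule (odd helix count ⇒ opposite-side termini).

## Worked example

The `analysis/` directory is a numbered workflow over the package. Step 1
simulates a study genome at the characterised repertoire composition
(197 genes; 3 CO2, 8 sugar, 2 GR43a-like, 184 bitter), steps 2–8 annotate,
classify, type, cluster, profile and search it:

```sh
Rscript analysis/01_simulate_genome.R
Rscript analysis/02_annotate_genes.R
Rscript analysis/03_classify_subfamilies.R
Rscript analysis/04_type_bitter_receptors.R
```

Step 4 prints the repertoire summary row (CO2, sugar, GR43a-like,
pseudogenes, typed bitter total, Type 1, Type 2, Type 3, untyped):

```
Summary row (CO2 sugar GR43a pseudo bitter T1 T2 T3 unknown):
  3 8 2 4 180 31 13 129 7
```

i.e. a 184-gene bitter clade of which 4 are pseudogenes, 31 Type 1,
13 Type 2, 129 Type 3 and 7 untyped partial models. Step 5 recovers the
implanted clusters — a 38-gene Type 3 tandem array spanning 0.152 Mb and a
9-gene Type 2 array spanning 0.037 Mb:

```
type2: 1 arrays; largest 9 genes on scaffold002 spanning 0.037 Mb
type3: 16 arrays; largest 38 genes on scaffold001 spanning 0.152 Mb
```

Step 6 profiles the 31-library expression panel (84 of 197 genes detected;
12 in embryos, 4 in 3rd instar, 12 in 5th instar, 18 in pupae, 20 across
larval tissues, 73 across adult tissues), and step 7 validates the topology
stage (implanted 3–7 helix proteins in the 200–350 aa regime are recovered
exactly). Step 3 reports 100% agreement between tree-based subfamily
assignment and the generator's truth, with bootstrap support 100 on the
subfamily-separating edges.

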