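---
title: "Methods: two-proteome gain/loss analysis with orthogain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-proteome gain/loss analysis with orthogain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthogain)
```

orthogain compares two annotated proteomes — call them species A and B —
and asks three questions that recur in comparative studies of unusual
phenotypes (the motivating case is a cancer-resistant rodent versus a
laboratory rat): which genes are shared and which are lineage-specific;
which protein families grew or shrank; and which pathways, pathway nodes
and source-to-phenotype routes are disrupted by the missing genes. A
fourth stage screens shared ortholog pairs for large (>25 residue)
insertions/deletions. Because studies of this kind rarely deposit a
reusable benchmark, the package includes a synthetic-data generator with a
ground-truth ledger; every stage of the pipeline is validated against
planted truth.

## Orthology model

**Representative isoforms.** Orthology operates at gene level. When a gene
has several protein records, the representative is chosen by smallest
protein-existence (PE) rank — an evidence level where 1 means
protein-level evidence — with ties broken by longest sequence, then by
smallest protein id. A missing PE rank sorts last. The lexicographic
tie-break is our addition (the convention in the source analyses stops at
length); it exists purely for determinism.

**Reciprocal best hits.** Hits with E-value above 1e-6 (inclusive cutoff:
E = 1e-6 survives) are discarded; per query the best subject is the
highest bit score, ties by lowest E-value, then lexicographic subject id
(the tie order is again ours, chosen for determinism — published RBH
analyses rarely state one). A pair is orthologous iff it is mutual-best in
both directions. Class I = paired genes, class II = A-only, class III =
B-only; the two conservation identities hold for every input and are
property-tested.

**Built-in aligner.** So that `run-all` needs no external binaries, the
package ships an affine-gap Smith–Waterman aligner (Rcpp): BLOSUM62, gap
open 11, extend 1, i.e. a gap of length L costs 11 + L, the BLAST
"existence/extension" convention. The E-value attached to each alignment
uses fixed Karlin–Altschul constants (lambda = 0.267, K = 0.041, the
standard gapped BLOSUM62-11-1 values) with search space m×n of the two
sequences. This is *not* a database E-value: it orders hits correctly and
makes the ≤ 1e-6 contract exercisable at desk scale, but it is no
substitute for a real BLAST run, which remains the documented path for
real data (import its 12-column tabular output). The aligner is tested
against two independent oracles: exhaustive path enumeration on tiny
strings and the Biostrings implementation on random pairs.

## Family dynamics

Each protein keeps only its best family assignment: smallest E-value at or
below 1e-5, ties by highest bit score then family id. Counting is by gene
after isoform collapse. The published family tables motivating this module
report, per family, counts for class I/II/III plus an "expanded" or
"contracted" column; the arithmetic identity `change = |class III| −
|class II|` holds for all 30 printed rows (shipped as a fixture and
regression-tested), so it is adopted as the *definition* of `delta`.
Class-I counting is per species (default: the B member of each pair is
counted), since a shared pair appears once in such tables; the choice only
affects the class-I column, never `delta`.

## Pathway analysis

**Gene-level enrichment.** Missing genes are the class-II set. For a
pathway with `n` background genes of which `k` are missing, against a
background of `N` genes containing `K` missing ones, the p-value is the
hypergeometric upper tail `P(X ≥ k)`, computed as a log-space sum of
`lchoose` terms (exact well beyond N = 1e5; `P(X ≥ 0) = 1` by
construction). The background defaults to all genes in the membership
table, with the whole proteome available via the `background` argument —
the source analyses do not state their background, and we flag rather than
guess which was used (their printed p-values are therefore *not*
reproduction targets). Significance is the raw p < 0.01, as in those
analyses; a Benjamini–Hochberg column is emitted alongside as a clearly
marked extension, not used for flagging.

**Node status and paths.** A pathway graph is a directed graph of nodes
holding gene sets, with phenotype sink nodes (empty gene sets allowed only
there). A node is `intact` when none of its genes is missing, `all_lost`
when all are (and it has at least one), `partial` otherwise. For path
affectedness the graph is restricted to nodes from which the phenotype
node is reachable; sources are the in-degree-0 nodes of that subgraph, and
all *simple* directed paths (no repeated nodes, so cyclic signalling maps
stay finite) from sources to the phenotype are enumerated by DFS, capped
at `max_paths` (default 10 000) with an explicit error on overflow. A path
is affected iff it contains a non-intact node. Whether curated map
"routes" are simple paths or edge-disjoint ones is not defined in the
motivating study; simple paths are our documented choice. The DFS is
validated against igraph's independent path enumeration on random DAGs,
together with monotonicity: growing the missing set never decreases the
affected count.

## Indel screen

For each class-I pair's alignment, a *gap run* is a maximal block of gap
columns on one side; a mismatch is a residue-vs-residue column with
different letters; the mismatch percentage divides by the full alignment
length, so identities + mismatches + gap columns = alignment length
(property-tested). A pair qualifies when its longest single run exceeds 25
columns **and** its mismatch percentage is strictly below 10 — both bounds
strict, exactly as printed in the source protocol; alignments with a
25-run or exactly 10% mismatches never produce events (tested on a
boundary grid). The "longest single run" reading (rather than summed gap
columns) follows the protocol's exemplars, which are contiguous segments;
`gap_mode = "total"` switches to the summed interpretation for sensitivity
analysis. Polarity is relative to species B: a gap on B's side is a
deletion in B, on A's side an insertion in B. Event coordinates are
1-based inclusive on the ungapped sequence that retains the segment, which
is also the protein whose domain annotations are intersected (≥1 residue
overlap; adjacency is not overlap). Optimal alignments place a gap
ambiguously when the segment borders an identical residue, so planted
events are matched by (pair, polarity, run length); coordinates are exact
on the generator's own alignments and may shift by ±1 after realignment.

Segment-absence verification translates the genome in six frames (offsets
0/1/2 on both strands, standard genetic code, stops re-coded to X so
alignments cannot span them profitably) and locally aligns the segment
against each frame; `present` requires ≥90% identity over ≥80% of the
segment. A 30-residue random segment never reaches that bar against a
random contig (negative-control test), so `absent` calls are meaningful at
these defaults.

## Synthetic data: what it emulates, and what it does not

The generator's defaults are the stated world of the package's tests: 100
shared ortholog pairs, 30 A-only and 20 B-only genes, representative
length ~300 residues (uniform ±30%, floor 130), per-residue substitution
rate 0.05 on the B copy, 10 shared pairs carrying one contiguous planted
indel of 30–40 residues placed ≥40 residues from either end (half inside
annotated domains), 20 families with rotating B-expansions / A-expansions
/ balanced membership, 6 pathways of 30 genes with a 12-node random-DAG
graph feeding one phenotype node, and 20% of genes carrying 2–3 truncated
isoforms with weaker PE ranks. Sequences use uniform amino-acid
composition — composition realism is irrelevant to the logic under test.
Simulated hit tables give every true pair a mutual best hit whose E-value
is a documented monotone function of identity and length (a pseudo bit
score `2·identity·length`), *not* Karlin–Altschul statistics; noise adds
spurious weak cross-hits (default E in 1e-3–1e-1, above the orthology
cutoff) and can redirect a fraction of forward best hits to decoys,
breaking reciprocity for exactly those pairs. One global seed drives a
named substream per component, so adding an output never perturbs others
and identical configurations are byte-identical.

A green recovery test therefore establishes that the *logic* — RBH,
classification, thresholds, bookkeeping — is correct under the stated
world. It does not establish robustness to real evolutionary processes:
no indel-rate calibration, no rate heterogeneity, no paralogy beyond
family decoys, no alignment-tool idiosyncrasies.

For the planted-enrichment criterion the spec fixes a 1000-gene
background, 28.5% missing genes and one pathway with 90% of its 30 genes
missing, but not the number of competitor pathways. We use 6 (one planted,
five null): with a conservative per-pathway false-flag rate of at most the
nominal 1%, the chance a replicate is perfectly clean is at least
0.99⁵ ≈ 0.951, which the discreteness of the hypergeometric comfortably
exceeds in practice — so requiring ≥95 clean replicates out of 100 is a
fair bar for the detector, not a tuned one.

## Numerical conventions

* **Percentages.** All one-decimal percentages go through
  `percent_one_dp()`: the ratio is rounded to two decimals, then to one
  with exact `.X5` halves rounded down. This two-stage convention is the
  only one that reproduces every percentage printed in the motivating
  study from its own integers — notably 15408/20835 = 73.952% printing as
  73.9 (a single nearest-integer round gives 74.0) while 15408/21553 =
  71.489% prints as 71.5 (so truncation is ruled out too).
* **Cutoffs.** E-value cutoffs are inclusive (≤); the indel gap bound
  (>25) and mismatch bound (<10%) are strict. These match the printed
  protocol exactly and are encoded once in `threshold_config()`.
* **Hypergeometric tail.** Log-space summation avoids underflow; values
  are clamped to [0, 1] against rounding at the extremes. Agreement with
  literal draw enumeration is exact to 1e-12 where enumeration is feasible
  (N ≤ 18 exhaustively in the suite) and with the reference distribution
  across N ≤ 60.
* **Determinism.** Every result table has a fixed column order and
  documented sort keys; re-running a stage writes identical bytes.
* **Degenerate inputs.** Empty alignment tables, empty missing sets,
  all-intact graphs, pathways with no background genes and empty
  annotation tables all return well-defined empty or zero results rather
  than errors; genuinely malformed inputs (wrong column counts, unknown
  node ids, negative E-values, double-gapped columns) fail loudly with
  the offending row or identifier named.

## Known limitations

* The built-in aligner is quadratic and intended for proteome sizes in the
  hundreds; real proteomes should come with precomputed tabular
  alignments.
* Orthology is strict one-to-one RBH: no many-to-many families, synteny or
  tree reconciliation, and mis-annotation in either proteome shows up only
  as inflated lineage-specific classes.
* Enrichment reports raw p-values by design (matching the protocol it
  follows); the BH column is advisory.
* The pathway-graph JSON dialect is purpose-built; curated KGML maps must
  be converted by the user.
* Printed real-data quantities that depend on unstated backgrounds or
  external database versions (enrichment p-values, family-universe counts,
  the published indel-pair total) are out of scope as numeric targets; the
  machinery behind them is validated on synthetic truth instead.
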