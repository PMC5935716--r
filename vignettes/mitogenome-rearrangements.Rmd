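---
title: "Models and methods: mitochondrial gene-order rearrangement analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: mitochondrial gene-order rearrangement analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorearr)
```

This vignette documents the models behind the package, the parameters that
matter, the design decisions taken where several formalizations were
defensible, and the known limits of each method. The running example is the
comparative analysis of two *Trichogramma* mitochondrial genomes against
the ancestral insect arrangement, whose annotation tables and reference
gene orders ship with the package.

## Gene orders as signed circular permutations

A mitochondrial gene order is modelled as a circular sequence of 37
oriented genes (13 protein-coding, 22 tRNA, 2 rRNA) plus an unsigned
control-region marker `CR`. Orientation is relative to the majority
strand, named by the ancestral convention (the strand carrying more genes
in the ancestral arrangement) and kept fixed across rearranged genomes —
so in *Trichogramma*, where most genes sit on the minority strand, the
strand labels still refer to the ancestral frame. `CR` carries no
orientation; all permutation-based computations exclude it by default and
it is re-attached for display and assembly.

Rotation of a circular order is a no-op (`orders_equivalent()` checks
equality up to rotation and, optionally, whole-molecule flip). Every
algorithm that needs a linear frame (`linearize()`) anchors the circle at a
named gene.

### Annotation tables and the size column

Feature coordinates are 1-based, fully closed. Between consecutive
features (wrap-around pair included) the intergenic gap is
`start_next - end_prev - 1`; negative values are overlaps. Published
annotation tables occasionally print a feature-size cell that contradicts
its own coordinates (transcription or typesetting slips). The package
stores both: positions drive everything positional (gaps, overlaps,
adjacencies, genome length), while coding totals sum the annotated size
column, which is what published totals are computed from;
`validate_annotation()` reports every row where the two disagree. In the
packaged *T. japonicum* table exactly one row (`nad2`) disagrees by 2 bp;
the derived positive-gap count (22) also differs from the published
"17 locations" while the total (547 bp) matches exactly — both numbers are
reported and the total is the quantity used downstream.

Features wrapping the origin are rejected with an explicit error: neither
packaged genome has one, and silently supporting them would complicate
every downstream interval computation for no data.

## Rearranged-gene classification

There is no universally agreed definition of "a rearranged gene". The
package encodes gene neighbourhoods as extremity adjacencies: each gene has
a head and a tail, a `+1` gene spans tail→head on the majority strand, and
the adjacency between consecutive genes is the unordered pair of meeting
extremities. This encoding is invariant under rotation and under inversion
of a block for adjacencies internal to the block.

The default rule: a gene is **rearranged** iff its strand differs from the
reference or neither of its two adjacencies occurs in the reference. The
rule was chosen because it is the only simple rule that simultaneously
(a) counts a gene that keeps both neighbours but flips strand (an in-place
inversion, like *nad2* in *Trichogramma*) as rearranged, and (b)
reproduces the published per-class counts for the packaged orders
(15 of 22 tRNAs, 7 of 13 protein-coding genes). Two alternatives are
available behind the `rule` argument: `"strict"` (any lost adjacency
counts) and `"position_only"` (orientation-blind).

The breakpoint distance is the number of adjacencies of one order absent
from the other; it is symmetric and zero exactly for equivalent orders.
The triangle inequality is checked empirically in the test suite, not
proven, since the gene-level encoding is not a metric by construction.

## Conserved segments and ancestral assembly

A conserved segment is a maximal run of genes contiguous, in the same
relative order and orientation, in every input order; by default an order
also carries a segment when it contains the whole segment inverted
(`allow_flip`), because an in-place inversion preserves the segment as a
unit of rearrangement.

`infer_ancestral()` formalizes the manual argument usually made in
comparative mitogenomics:

1. Segments shared between any ingroup member and an outgroup are fixed as
   ancestral.
2. Derived segments shared within the ingroup are fixed next. Support is
   counted over *arrangement classes*: ingroup orders with equivalent
   arrangements collapse into one carrier, because identical sister taxa
   are a single character state and cannot corroborate themselves.
3. A qualifying derived segment may be *extended* within a single carrier
   across neighbouring strand-changed genes whose joining adjacencies are
   also present in the outgroup. This captures the classic "bigger
   inverted block" argument: when one lineage shows a larger in-place
   inversion whose interior adjacencies match the ground pattern, the
   larger block is the more plausible ancestral unit. Growth stops at the
   first gene that retains its ancestral strand or joins across a
   non-ancestral adjacency.
4. Uncovered genes default to the first outgroup's arrangement.

Placement is greedy: longer segments outrank shorter; at equal length,
shared-with-outgroup outranks ingroup-only; remaining ties go to the
first-listed carrier. Segments are stitched in the order their gene
content occupies in the first outgroup, and `CR` is re-attached after the
gene it follows in that outgroup (segments may wrap the circular origin,
so appending it at the end of the linear frame would be wrong).

On the packaged chalcidoid fixtures this assembly reproduces the packaged
presumed chalcidoid ancestral order exactly, and on synthetic clades
(one operation of each kind applied to a known ancestor, operations
confined to disjoint regions) it recovers the ancestor in 100 of 100
seeded trials. The disjointness matters: two taxa hit by overlapping
operations can coincide on a shared derived arrangement, and a
support-based method must then — correctly, given its evidence — call that
arrangement ancestral. This is a limit of the evidence, not of the
implementation.

## Rearrangement scenarios from strong interval trees

Two gene orders over the same gene set, linearized at a common anchor
(default `cob`, which keeps its orientation and context in both packaged
orders), define a signed permutation: the reference reads as the identity.
A common interval is a set of consecutive values occupying consecutive
positions; a strong interval overlaps no other common interval; the strong
intervals form a tree whose internal nodes are labelled linear-increasing,
linear-decreasing, or prime by the order of their children.

The scenario heuristic assembles operations forward from the source:

* a node whose content is the exact reversal of its sorted block is one
  **inversion**;
* a linear-decreasing node is resolved by a dynamic program over its child
  ranges, combining whole-range inversions, end-child **transpositions**,
  moves of maximal runs of fully inverted children as single
  **inverse transpositions**, per-child inverse transpositions out of an
  increasing child, and a TDRL fallback — the cheapest route wins;
* inside prime nodes, runs of value-adjacent fully inverted children are
  rectified by single inversions; a child block that is badly out of place
  may be *extracted* as a transposition or inverse transposition when that
  reduces the TDRL count (the extracted block rides glued to a neighbour
  through the duplication-loss steps and is placed last); the remaining
  child blocks are sorted by a minimal sequence of **TDRL** steps.

TDRL sorting uses the radix construction: with `r` maximal runs of
consecutive values at increasing positions, `ceiling(log2(r))`
duplication-loss steps suffice, each step a stable binary partition by one
bit of the run index; the test suite verifies this length equals the
exhaustive minimum for every permutation up to n = 6. When `r` is not a
power of two the labelling has slack, which `enumerate_scenarios()`
exercises to produce genuinely distinct co-optimal scenarios; equal-cost
route choices in the dynamic program are a second tie-point. Reported
scenarios are deterministic: ties fall to a fixed route order.

Soundness is enforced unconditionally: every emitted scenario is replayed
twice (once over the value permutation, once gene-by-gene on the actual
source order) and must reproduce the target exactly.

On the packaged pair the heuristic finds eight operations — one
transposition (rrnS), two inverse transpositions (trnM; nad2 + trnW), two
inversions (trnI; the trnA–trnS1 cluster) and three TDRLs — and at least
two distinct co-optimal eight-operation scenarios exist.

### Limits

The heuristic is node-local. Histories of two or more operations with
overlapping spans can yield permutations whose only minimal explanation
uses a block that properly crosses a strong interval, which no
decomposition along the tree can express; the inferred scenario is then
longer than the true history (observed in roughly 5–10% of seeded
two-to-three-operation histories, never for single operations). Exact
parsimony over all four operation kinds is NP-hard and out of scope; the
package trades optimality for determinism, soundness and interpretability,
like the tool family it follows.

## Sequence features

Skews are computed on the given (majority) strand with ambiguity codes
excluded; degenerate denominators yield `NA` rather than errors. RSCU uses
the invertebrate mitochondrial code (translation table 5); stop codons are
counted but excluded from RSCU; a family with no observations reports
`NA`. A trailing 1–2 nt remainder is accepted as a truncated stop (`T`,
`TA`) — anything else is a frame error naming the sequence.

The tandem-repeat scan compares the sequence against itself at every
candidate lag, reports maximal matching runs as repeats with fractional
copy number, optionally bridges interrupted repeats while the mismatch
fraction stays within budget, and suppresses hits nested inside an
equal-or-better hit at a shorter unit (so a perfect `(TA)40` is one hit of
unit 2, not also hits at lags 4, 6, ...). It is a deliberately simple,
fully deterministic scan — not a reimplementation of alignment-scored
repeat finders — and its acceptance checks use constructed inputs.

Control-region element thresholds are not standardized in the literature;
the defaults are: polyT ≥ 5 T; `[TA(A)]n` ≥ 3 units; stem arm 5–20 bp
with loop 3–30 nt and ≤ 1 mismatched pair (longest arm wins); `G(A)nT`
with 1 ≤ n ≤ 6; G+A-rich = maximal segment of ≥ 10 nt with ≥ 80% G+A.
All are arguments; absent elements are reported as absent, never errors.

## The synthetic-data generator

`simulate_orders()` applies a configured number of operations to a base
order (default: the packaged chalcidoid ancestral order), sampling kind by
weight, block endpoints uniformly on the linearized order (the anchor
itself never moves, so ground truth lives in a fixed frame) and block
lengths geometrically (`block_p`, default 0.25, mean 4 genes — typical of
observed mitogenome rearrangement units, which are mostly short tRNA
blocks with occasional long stretches).

Sampled operations are conditioned on being **observable and diagnostic of
their kind**: draws that would leave the order unchanged are rejected; an
inverse transposition must genuinely displace its block (otherwise it is
an inversion); and a TDRL keep pattern must contain at least five
alternation runs, because patterns with fewer are expressible as an
identity or a single transposition, and a ground-truth label claiming
"TDRL" for such an outcome would be meaningless. Uniform per-gene
keep-sampling without this conditioning frequently produces
transposition-equivalent outcomes, making kind-recovery rates ill-posed.
Under these conditions the scenario heuristic recovers the kind of a
single simulated operation in ≥ 95% of 200 seeded trials (100% in the
packaged test run).

`simulate_genome()` lays the 37 genes plus control region along a molecule
of configured length with configurable spacers/overlaps, and draws the
sequence with *exact* base counts matching the target A+T content (default
84%) and skews (defaults +0.05 AT skew, −0.25 GC skew on the majority
strand — the A-over-T and C-over-G bias typical of apocritan
mitogenomes), shuffled uniformly. Requested tandem repeats and
control-region elements are written into the control region at recorded
positions. The generator emulates composition, layout and embedded motifs
only; it does not simulate substitution or indel evolution, real codon
structure inside genes, or replication-origin-driven skew gradients — so
passing recovery tests demonstrate correctness of the detectors, not
realism of mitochondrial sequence evolution.

## Problem sizes in the packaged checks

The test suite verifies the strong-interval tree against brute-force
enumeration for every permutation up to n = 8 plus 500 random n = 10
cases; TDRL minimality against exhaustive graph search for every
permutation up to n = 6; coverage identities on both packaged annotation
tables and 100 simulated genomes; single-operation recovery over 200
seeded trials; and ancestor recovery over 100 seeded four-taxon clades.
These sizes were chosen so the whole suite completes in a few minutes on
one core while the exhaustive parts remain genuinely exhaustive.

## Known limitations

* Reference orders for taxa whose arrangements are published only as
  figures are best-effort transcriptions, flagged
  `metadata$confidence = "figure"`; analyses quoting them should treat
  segment boundaries inside unflagged regions as reliable and cluster-
  internal tRNA placements as approximate.
* Sequence-level statistics of the real genomes (A+T percentages, codon
  tables of the actual molecules) require the deposited sequences, which
  are not packaged; the packaged checks use constructed and simulated
  sequences only.
* tRNA secondary-structure folding, gene annotation, and sequence-based
  phylogenetics are out of scope; annotations are taken as given.
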