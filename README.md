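# mitorearr

Comparative analysis of mitochondrial genomes built around signed circular
gene orders, for people studying gene rearrangement in animal — especially
insect — mitogenomes. The package grew out of the comparative analysis of
two *Trichogramma* egg-parasitoid (Hymenoptera: Chalcidoidea) mitochondrial
genomes, whose annotation tables and gene orders ship as fixtures, but every
function works on any annotated mitogenome or gene order.

## What it computes

**Annotation metrics.** From a feature table (gene, strand, 1-based
start/end) on a circular genome: intergenic and overlapping nucleotides per
adjacent pair (`adjacency_records()`), genome summaries (`summarize_genome()`
— totals, longest spacer, coding fraction, tRNA size range), and per-class
strand usage (`strand_census()`).

**Sequence features.** Nucleotide composition with the strand-asymmetry
skews AT skew = (A − T)/(A + T) and GC skew = (G − C)/(G + C)
(`composition()`); codon usage and relative synonymous codon usage under
the invertebrate mitochondrial code, RSCU(c) = n_c · |family| / Σ n
(`codon_usage()`); strand-aware start/stop-codon extraction including the
truncated `T`/`TA` stops (`extract_terminal_codons()`); a self-contained
tandem-repeat scan (`find_tandem_repeats()`) and a control-region element
scan — polyT stretch, [TA(A)]n, stem-loop, TATA and G(A)nT motifs,
G+A-rich segment (`scan_control_region()`).

**Rearrangement analysis.** Gene orders are signed circular permutations.
Extremity adjacencies (head/tail pairs) give a breakpoint distance
(`breakpoint_distance()`); a gene is classified rearranged relative to a
reference when its strand changed or neither of its adjacencies is
preserved (`classify_rearranged()`); maximal conserved segments across
any number of orders, counting whole-segment inversions as conserved,
come from `shared_segments()`.

**Ancestral gene orders.** `infer_ancestral()` assembles a presumed
ancestral arrangement for a clade from conserved segments: segments shared
with an outgroup are fixed first, derived segments shared within the
ingroup next (longer segments outrank shorter; an in-place inversion can be
extended across outgroup-consistent interior adjacencies), and leftover
regions default to the outgroup ground pattern.

**Rearrangement scenarios.** `infer_scenario()` reconstructs an ordered
operation list — inversions, transpositions, inverse transpositions, and
tandem-duplication-random-loss (TDRL) events — transforming one order into
another, from the strong interval tree of their common intervals (the
heuristic popularized by CREx). Prime nodes are sorted by a minimal
⌈log₂ r⌉ radix sequence of TDRLs; every emitted scenario is replayed
against the target and must reproduce it exactly.
`enumerate_scenarios()` lists co-optimal alternatives.

**Synthetic data.** `simulate_orders()` applies seeded, kind-diagnostic
rearrangement operations to a base order and returns the ground-truth
scenario; `simulate_genome()` draws an annotated genome sequence with
controlled length, A+T content, skews, embedded tandem repeats and
control-region elements.

## Worked example

```r
library(mitorearr)

tj <- read_annotation_tsv(mitorearr_example("tjaponicum_annotation.tsv"))
summarize_genome(tj)[, c("genome_length", "total_intergenic", "longest_spacer",
                         "total_overlap", "pcg_total_length", "pcg_fraction")]
#>   genome_length total_intergenic longest_spacer total_overlap pcg_total_length pcg_fraction
#> 1         15962              547             81            19            11202        70.18
```

The *T. japonicum* genome is 15,962 bp with 547 bp of intergenic
nucleotides (longest spacer 81 bp, between *atp8* and *trnD*), 19 bp of
overlaps at five gene junctions, and 11,202 bp of protein-coding sequence
(70.18% of the genome).

```r
cl <- classify_rearranged(order_from_annotation(tj), reference_orders("PanGO"))
rearrangement_counts(cl)
#>   class rearranged total
#> 1   PCG          7    13
#> 2  rRNA          1     2
#> 3  tRNA         15    22
```

Against the ancestral insect arrangement, 15 of 22 tRNA genes and 7 of 13
protein-coding genes are rearranged (*nad2* keeps its neighbours but counts
as rearranged because it switched strands).

```r
sc <- infer_scenario(reference_orders("ChalcidoidGO"),
                     reference_orders("TrichogrammaGO"))
glance(sc)
#>   n_ops inversions transpositions inverse_transpositions tdrls anchor
#> 1     8          2              1                      2     3 cob
scenario_narrative(sc)[1:5]
#> operation 1: transposition of [-rrnS] to before V
#> operation 2: inverse transposition of [M] to before Q
#> operation 3: inverse transposition of [nad2 W] to after M
#> operation 4: inversion of [I]
#> operation 5: inversion of [A R N S1]
```

Eight operations — one transposition (rrnS), two inverse transpositions
(trnM; nad2 + trnW), two inversions and three TDRLs — transform the
presumed chalcidoid ancestral order into the derived *Trichogramma* order.

A thin command-line wrapper over the same functions is installed under
`exec/mitorearr` (`stats`, `compare`, `scenario`, `ancestral`, `simulate`
subcommands; see `run_pipeline()`).

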