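---
title: "Models and methods in dsrnatk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in dsrnatk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsrnatk)
```

dsRNA-seq couples a single-strand-specific ribonuclease digestion with
strand-specific sequencing: whatever survives the digestion and ends up in
the library was base-paired, either within one molecule (a fold-back) or
between two (a heteroduplex). This vignette explains the statistical
models behind each analysis step, the tunable parameters and their
defaults, what the bundled simulator does and does not emulate, and the
design choices made where the methodology left room.

## Reads, weights and coverage

Raw reads are collapsed to non-redundant (NR) sequences with a clone
count, and 3' adapters are removed by exact-match search: the leftmost
position where a prefix of the adapter (at least `min_overlap = 5` nt)
runs to the end of the read marks the junction; reads without a
recognizable adapter are kept unchanged, and products shorter than 15 nt
(configurable) are discarded as unmappable. Exact matching is
deterministic and desk-checkable; one mismatched adapter base leaves a
read untrimmed, which for short-insert libraries merely shifts a small
fraction of reads into the "untrimmed" pool rather than corrupting
coordinates.

An NR sequence mapping to `n_hits` genomic positions contributes weight
`copies / n_hits` to each placement, so the genome-wide weight of a
sequence always sums to its clone count and library mass is conserved
through every downstream aggregation (classification counts, bin weights,
coverage mass). Counting each placement fully would inflate repetitive
regions by their copy number; discarding multi-mappers would blank out
exactly the transposon biology this assay is sensitive to. Coverage is
accumulated per base and strand; unstranded reads fall to the plus array.

## Classification and strand bias

A read overlapping several features gets the single highest-priority
category, with ties broken by the larger overlap, then the leftmost
feature. The default priority — rRNA, tRNA, snoRNA, snRNA, miRNA,
transposable element, CDS exon, 5' UTR, 3' UTR, intron, other ncRNA,
intergenic — puts structural ncRNAs first because they are frequently
encoded inside the introns and UTRs of protein-coding genes and dominate
the base-paired signal; the order is a function argument, not a constant.

Strand bias is reported as Lods = log10((S + c)/(A + c)) with pseudocount
c = 1: a decade scale, so +2 means a hundred-fold sense excess, and the
pseudocount keeps single-strand categories finite. A covered locus is
typed `inter` (heteroduplex) when both strands carry at least 5 units of
weight and the minority strand holds at least 20% of the total, `intra`
otherwise. Both thresholds are exposed; they were chosen once as the
weakest evidence one would accept for physical presence of both strands,
and the call is monotone in the minority weight by construction.

## The geometric hotspot model

Covered segments — maximal runs of bases with combined-strand depth > 0 —
are the observation unit. Their lengths are modelled per chromosome as
geometric on {1, 2, ...}: memorylessness is the natural null for coverage
that starts and ends at random, and the per-chromosome fit absorbs
differences in expression density (organellar chromosomes, pericentromeric
repeats). The method-of-moments estimator p̂ = 1/L̄ is exact for this
family; a chromosome with fewer than two segments falls back to the
pooled genome-wide fit. The tail probability of a segment of length L is

P(X ≥ L) = (1 − p̂)^(L−1),

and hotspots are segments whose Benjamini–Hochberg q-value is at most
α = 0.05 across all tested segments genome-wide. Segments supported by
fewer than 2 distinct reads are not tested — a single clone can span an
arbitrary length without constituting replicated evidence. Hotspot ids
(`chr1_h7`) number the calls per chromosome in coordinate order; strand
composition is recorded as an attribute of the call, not a partition,
since segments are built on combined-strand coverage (a fold-back and a
heteroduplex should both surface as one covered unit). Small-RNA hotspots
use the identical machinery on the smRNA library, and novel transcription
units are hotspots with zero annotated overlap, flagged by ≥1 bp overlap
with smRNA hotspots.

## Differential windows and substrate calls

The genome is tiled with non-overlapping 1 kb bins (a `--step` smaller
than the width turns this into a true sliding window; tiling is the
default because overlapping windows share reads and complicate the
multiple-testing landscape). Read weight is apportioned to bins by
fractional overlap, which conserves mass exactly. For each bin the fold
change compares per-million-normalised weights with a pseudocount of 0.5
on both counts (stabilising empty bins), and significance comes from a
two-sided Fisher's exact test on the rounded 2×2 table of bin weight
versus remaining library weight — exact at any depth, assumption-free for
unreplicated designs, and verifiable against full hypergeometric
enumeration, which the test suite does. A bin is called at fold ≥ 2 and
p < 0.001 in either direction; adjacent same-direction calls merge into
regions. Substrate calls are bins significant in the A>B direction in
both the dsRNA and the smRNA assay — regions whose double-stranded RNA
and small-RNA output both depend on the genotype difference, the
signature of an RDR substrate.

## Phasing

Processive dicing in 21-nt steps from a defined end concentrates
small-RNA 5' ends on one residue class modulo 21. A window of m = 9
cycles has 189 slots; a slot is occupied when at least one 5' end lands
on it (duplicates count once), minus-strand 5' ends are shifted +2 nt for
the 2-nt 3' overhang of siRNA duplexes, and only 20–22 nt reads
participate. If n slots are occupied in total and k of them fall in the
fullest register, the score is the hypergeometric upper tail
P(K ≥ k | n draws, m of m·D slots in the register), multiplied by D for
the registers examined (Bonferroni) and capped at 1. Windows slide in
21-nt steps across a locus and the best window is kept; windows with
fewer than 4 occupied slots are not tested, so sparse loci cannot reach
vacuous significance. The occupancy formulation deliberately discards
read abundance: one heavily amplified siRNA should not make a locus
"phased". The threshold of 1e-3 on the adjusted p keeps the family-wise
null rate well below 5%, which the null simulation confirms.

## Conservation

Per-base conservation scores arrive as a bedGraph (any monotone per-base
score works; the multi-species alignment that produces it is upstream of
this package). Within each structural moiety the hotspot bases and the
complementary flanking bases are emitted as maximal intervals, each
region's mean score is computed over its scored bases, regions with fewer
than 10 scored bases are dropped (unstable means), and the two sides are
compared with a two-sided Wilcoxon rank-sum test on per-region means.
Regions, not bases, are the sampling unit because neighbouring bases are
strongly autocorrelated; treating bases as independent would overstate
significance by orders of magnitude. Direction is the sign of the median
difference.

## Structure models

The constraint rule is a direct translation of the assay: a transcript
position covered by at least one dsRNA read was base-paired in solution,
so it is constrained '|' (must pair with someone — not with a named
partner); uncovered positions stay '.'. Minus-strand transcripts read
their genomic coverage reversed so the constraint string runs 5'→3'.
Two engines consume the string. The thermodynamic adapter shells out to
RNAfold with default parameters and passes the constraint line verbatim,
returning the MFE structure and its free energy in kcal/mol. The built-in
engine is a constrained Nussinov dynamic program: maximum base pairs over
{AU, UA, GC, CG, GU, UG} with a minimum hairpin loop of 3, where a '|'
position that ends a subproblem unpaired renders that subproblem
infeasible. Infeasible constraints raise an error listing the offending
positions — they are never silently relaxed, because a silently dropped
constraint would misrepresent the data. Traceback prefers pairing the
left end with its smallest admissible partner, making outputs
reproducible to the byte. Per-base read densities attached to models are
depth divided by the number of covered transcript bases, the
normalisation used for rendering. CT and dot-bracket files round-trip the
pair table exactly.

## The simulator, and what passing tests mean

`simulate_dataset()` builds: a uniform-random genome; an annotation with
the standard categories including mRNAs cut into UTR5/CDS/intron/CDS/UTR3;
background covered segments with geometric lengths (default mean 40 nt,
20,000 segments on a 1 Mb two-chromosome genome) placed with at least 1 nt
between them so the observed maximal runs are exactly the drawn lengths;
50 planted 400-nt fully covered hotspots; a trailing differential zone per
chromosome holding 1 kb bins planted at 4-fold excess (10 in both assays,
5 dsRNA-only, 5 smRNA-only, ~50 expected weight on the low side — enough
depth for the Fisher test to resolve a 4-fold change); phased 21-nt reads
in 3 of the double-planted bins; and a conservation track of 0.2 ± 0.05
(background) versus 0.9 ± 0.05 (hotspots), clipped to [0, 1]. Libraries
are paired: background reads are identical in the A and B libraries so
only planted bins differ, which isolates the test's calibration from
background sampling noise; the independent-sampling case is covered
separately by `simulate_window_pair()`. One integer seed drives derived
sub-streams per component, so outputs are byte-identical across runs and
every planted element is recorded in a truth manifest.

The generator reproduces the *geometry* of the assay — segment lengths,
strandedness, fold changes, register structure — not its chemistry: no
sequencing errors, no mappability gaps, no partial nuclease digestion, no
expression-correlated coverage, and planted hotspots are uniform and
fully covered where real ones are ragged. Passing tests therefore
demonstrate that the estimators and callers recover what their models
describe at realistic sizes and depths, not that those models capture
every artefact of a real library.

Default problem sizes (1 Mb genomes, 10,000-bin calibrations, 1,000-locus
phasing nulls, folding oracles at length ≤ 12) were chosen as the
smallest scales at which every statistical property under test is
well-resolved; all are configuration fields.

## Numerical and edge-case conventions

Coordinates are 0-based half-open everywhere inside the package; GFF3 is
converted at the boundary. Geometric tails are computed in closed form
(no summation error); BH correction uses `p.adjust`. Fisher tables round
fractional weights to integers — exactness of the test outweighs the
sub-read rounding, and the pseudocounted fold gate is unaffected.
`test_bin` with two empty counts returns fold 1, p 1 rather than testing
nothing. Fitting a geometric to a single segment is refused with a
pointer to the pooled fallback; a degenerate fit (all lengths 1) gives
p̂ = 1 and zero tails for L > 1. Phasing refuses loci shorter than one
cycle and windows with no occupied slot. Empty saturation fractions,
all-zero duplex weights and unscored conservation regions raise or skip
with explicit notes rather than returning silent zeros.

## Known limitations

The adapter trimmer is exact-match only; the hotspot model assumes
segment lengths are identically distributed within a chromosome, which
breaks if coverage density varies wildly within one chromosome; Fisher's
test treats reads as independent draws, so clonal amplification not
removed by NR collapsing would overstate significance; the phasing
statistic does not model the miRNA-guided cleavage site that anchors real
phase registers; and the built-in folding engine maximises pair count,
not free energy — it is a verification instrument and a fallback, while
thermodynamic folding should use the RNAfold adapter.
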