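---
title: "Characterizing microsatellite landscapes with ssrscape"
author: "ssrscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing microsatellite landscapes with ssrscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrscape)
```

## The problem

Microsatellites (simple sequence repeats, SSRs) are perfect tandem
repetitions of short DNA units. Their density and motif spectrum differ
strongly between genomes and between genomic compartments — intergenic space
is typically repeat-rich, coding sequence repeat-poor and dominated by
trinucleotides (which preserve reading frame) — and comparative SSR surveys
are a routine step in characterizing new assemblies, for example across bat
species with very different genome sizes. `ssrscape` packages the complete
survey: mining, motif classification, compound merging, region statistics,
gene positional profiling, and two-genome comparison, with a synthetic-data
generator that makes every step verifiable against planted truth.

## The mining model

An SSR is a maximal perfect tandem run of a *primitive* unit (one that is
not itself a repetition of a shorter unit) of length $k \in \{1,\dots,6\}$,
reported when its whole-unit repeat count $r$ reaches the per-unit-length
minimum. The defaults are the MISA-convention thresholds used across
vertebrate genome surveys:

| unit length $k$ | 1 | 2 | 3 | 4 | 5 | 6 |
|---|---|---|---|---|---|---|
| minimum $r$ | 12 | 6 | 5 | 5 | 4 | 4 |

Key semantics, each of which the brute-force oracle in the test suite checks
exhaustively:

* **Maximality and anchoring.** A run cannot be extended by a full unit on
  either side, nor slid left by one base; trailing partial units are not
  counted toward $r$ and are outside the record span. Record length is
  always $k \times r$.
* **Primitivity.** A run qualifies only under its primitive unit: a poly-A
  tract is one mononucleotide SSR, never also $(AA)_n$.
* **Hard breaks.** N and any other non-ACGT character terminates runs
  (mining never errors on them); lowercase (soft-masked) sequence is mined
  normally.
* **One SSR per position.** In the rare case where two maximal runs of
  different unit lengths overlap by a few bases (the tail of a poly-A tract
  seeding an $(AC)_n$ run, say), records are accepted greedily by start
  coordinate, longer span first. The tie rule is arbitrary but deterministic,
  and the independent oracle implements the same published rule.

The scan itself is vectorized: for each $k$ the sequence is compared with
itself shifted by $k$; maximal runs of equality are maximal periodic regions,
and whole-unit counts fall out of the run lengths. This is $O(6n)$ and mines
a 500 kb contig in well under a second.

**Compound SSRs.** Two neighbouring SSRs whose gap is *strictly* less than
100 bp (`start(next) − end(prev) − 1 < 100` in 1-based closed coordinates)
are chained, transitively, into one compound locus. A 99 bp gap merges; a
100 bp gap does not. Compound members still count individually in all
summary statistics, which is the reading under which per-unit-length counts
sum to published totals; compounds are reported separately.

## Motif classes

Repeat units that are cyclic rotations and/or reverse complements of one
another describe the same repeat tract read in a different frame or from the
other strand, so they are identified: the AAG class is
{AAG, AGA, GAA, CTT, TTC, TCT}; the GCGT class has eight members. A class is
labelled by its lexicographically smallest member, which is deterministic
and testable. Published tables often label a class by another representative
(CT for the AG class, TAT for the AAT class), so summaries also carry an
`alias` — the most frequent observed spelling in the data — allowing either
rendering without guessing any table's convention. Class counts for unit
lengths 1–6 are 2, 4, 10, 33, 102, 350, verified in the tests against an
independent union-find partition of all $4^k$ strings.

## Region statistics

From GFF3 (gene → mRNA → exon/CDS with ID/Parent attributes, the NCBI RefSeq
dialect) six interval sets are derived, each merged before lengths are
summed: gene spans; intergenic (per-sequence complement of gene); exon
(union over all transcripts); intron (per-transcript span minus exons,
unioned); CDS; and UTR (exon of *coding* transcripts minus CDS — transcripts
without CDS contribute no UTR). The categories are deliberately nested, so
an SSR is counted in **every** category it overlaps by at least 1 bp: one
straddling an exon/intron boundary counts in exon, intron and gene.
Exclusive assignment would contradict the nesting (exon ⊇ CDS ∪ UTR) and is
not attempted. Densities are counts per Mb of the category's merged length;
genome-level denominators include N bases, matching how published surveys
divide by total assembly length.

Multi-transcript genes use unions across transcripts (a base exonic in any
transcript is exonic; intronic in any transcript, intronic). This is
order-independent — region sets are invariant to shuffling GFF3 lines — and
was chosen because exon unions are the only convention that needs no
designated transcript.

## The 13-element positional profile

Genes with more than six exons (i.e. ≥ 7, which forces ≥ 6 introns) are
divided, 5′→3′ and strand-aware, into: 500 bp upstream; exon 1, intron 1,
exon 2, intron 2; the remaining "middle" exons split into a left and a right
half around the pooled middle introns; the last-second intron and exon; the
last intron and exon; and 500 bp downstream. Flanks are clipped at sequence
ends. Where the filter and element names leave details open, the package
fixes them deterministically:

* the odd middle exon goes to the *left* (5′) half — the split is at the
  midpoint of the ordered middle-exon list and is strand-symmetric;
* all middle introns are pooled under one label;
* the partition is defined down to 6 exons (one exon per middle half), the
  floor at which all 13 labels exist; the default selection filter stays
  at 7.

The relative position of an SSR inside an element is
$$ v = \frac{\text{offset of the SSR's 5′-proximal end from the element's
5′ end}}{L - \ell} \in [0, 1], $$
with $L$ the element length and $\ell$ the SSR length, binned into
right-closed tenths P0.1–P1.0 ($v = 0$ falls in P0.1). When $L = \ell$ the
formula divides by zero and $v$ is defined as 0.5, the only strand-symmetric
choice. SSRs spanning an element boundary are counted once — in the element
holding the larger share, ties to the 5′ element — and carry no bin, so that
per-label bin counts always sum to the label's contained-SSR count.
Per-label abundance is count per Mb of the label's summed length across
profiled genes.

## The synthetic generator

`simulateSSRGenome()` emulates exactly the features the survey depends on:
multi-sequence assemblies with N runs, gene models with 7–9 exons on both
strands (gene → mRNA → exon/CDS, CDS trimmed 120 bp inside the outermost
exons so both UTRs exist), and planted perfect SSRs of all six unit lengths
with known coordinates, classes, repeat counts, region categories, element
labels and position bins. Construction guarantees, rather than samples, the
properties the tests assert:

* the background is uniform-random ACGT *sterilized* to a fixed point —
  detected runs are broken by single substitutions and re-checked — so the
  only SSRs present are the planted ones;
* planted runs get flanking bases adjusted so they are maximal and
  left-anchored, making coordinate *equality* (not just overlap) assertable;
* plants are mutually separated by more than the compound gap, except one
  explicitly requested intergenic pair 50 bp apart that must merge into
  exactly one compound;
* element windows and region categories in the truth table are computed from
  the generator's own interval bookkeeping, written independently of the
  annotation and profiling modules.

Everything is a pure function of the seed and arguments. The full-scale
configuration used in the acceptance checks is 2 × 500 kb sequences, 16
genes, ~218 planted SSRs (one per element per gene, plus intergenic, N-run
and compound extras) — large enough to cover all 13 labels, all six unit
lengths, both strands and all six region categories, and it runs in seconds.
What the generator deliberately does **not** emulate: realistic base
composition, isochores, transposon-associated SSR clustering, imperfect or
interrupted repeats, and overlapping gene models. Passing the planted-truth
checks therefore demonstrates the correctness of the interval arithmetic and
mining semantics, not robustness to every quirk of real annotation.

## Published-survey arithmetic

The package ships the raw published genome-survey counts for two bat
assemblies (*Pteropus vampyrus* Pvam_2.0 and *Miniopterus natalensis*
Mnat.v1) as plain data — counts, summed lengths, genome sizes, per-motif
counts — and the tests recompute every derived value (abundance, both senses
of frequency, SSR content) from them through the package's own formulas,
at half-up 2-decimal display rounding with full precision retained
internally. "Frequency" is disambiguated as `frequency_of_total` (a unit
length's share of all SSRs) versus `frequency_within_unit` (a motif class's
share of its unit-length category); published per-motif tables list only the
top motifs, so `motifClassSummary(..., unitTotals =)` lets the denominators
be the full category totals. One published value is arithmetically
off-by-one-in-the-last-digit (a borderline half-up case reproduced in the
test comments); all others reproduce exactly. The published genome-scale
*raw* counts themselves are inputs, not targets — reproducing them would
require mining the multi-gigabase assemblies.

## Numerical and interface choices

* Coordinates are 1-based closed throughout (the native IRanges/GRanges
  convention); GFF3 and MISA-style TSV output are 1-based inclusive as those
  formats require.
* Display rounding is half-up (`roundHalfUp()`), matching all checked
  published values; internal computation never rounds.
* Bin indices use `ceiling(round(v * 10, 9))` so values sitting exactly on a
  bin boundary (0.1, 0.2, ...) are not pushed upward by floating-point
  noise.
* Problem sizes in the tests: oracle equivalence uses 1000 random sequences
  of length ≤ 300 over mixed alphabets (uniform ACGT, repeat-prone
  two-letter, N-bearing, soft-masked); the planted-recovery check uses the
  1 Mb / 16-gene configuration above. Both finish in seconds to a couple of
  minutes on one core.

## Limitations

Interrupted/imperfect repeats beyond compound merging, unit lengths above
6 bp, and IUPAC-ambiguity motifs are out of scope. Region definitions assume
transcripts carry exon rows and coding transcripts carry CDS rows within
exons; annotations violating that are rejected rather than repaired.
Functional annotation of SSR-bearing genes (GO/KEGG style) is outside the
package: it depends on external protein and pathway databases, not on
computation the survey itself defines.
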