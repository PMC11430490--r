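---
title: "mitoprofile: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitoprofile: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoprofile)
```

## The problem mitoprofile addresses

A vertebrate mitochondrial genome is a circular molecule of roughly
16.5 kb carrying a nearly invariant complement of 37 genes — 13
protein-coding genes (PCGs) of the oxidative-phosphorylation chain, 22
tRNAs, 2 rRNAs — plus one major non-coding control region (D-loop).
Descriptive mitogenomics papers characterize a newly assembled mitogenome
with a standard battery of statistics (gene inventory, intergenic spacers
and overlaps, base composition and strand skews, codon usage, control
region motifs and tandem repeats) and, increasingly, compare it
base-by-base against conspecific genomes to quantify intraspecific
divergence. `mitoprofile` implements that battery as a tested, scriptable
pipeline over explicit domain types, so the numbers in such a
characterization can be recomputed, audited, and validated against
synthetic genomes with known ground truth.

The reference gene arrangement shipped with the package
(`default_layout()`) is the annotation of the grey-shanked douc langur
(*Pygathrix cinerea*) mitogenome: 16,541 bp, with the control region
spanning the sequence origin (positions 15,584–16,541 continuing at
1–136, 1,094 bp) and the characteristic 22 bp `atp8`/`atp6` overlap.

## Coordinate conventions

All coordinates are 1-based and fully inclusive on the heavy (H) strand —
the convention of published mitogenome feature tables, so a printed table
row can be used as input without translation. A feature with
`stop < start` wraps through the origin and is modelled as a *single*
record; its length is `(L - start + 1) + stop`. Minus-strand (L-strand)
features are extracted as the reverse complement of their annotated span,
so every extracted gene is in coding/structural orientation.

The signed gap between consecutive features is
`downstream_start - upstream_stop - 1`, normalized into `(-L/2, L/2]` so
pairs spanning the origin (in either direction) get their true circular
gap. Negative gaps are overlaps. With this convention the circle closes
exactly: summed feature lengths plus summed signed gaps equal the genome
length, a conservation law the test suite checks on the reference layout
and on randomized layouts.

## Composition statistics

For any region the package reports base counts, A+T content
`(A+T)/(A+C+G+T)`, and the two strand-asymmetry statistics

$$\mathrm{AT\text{-}skew} = \frac{A - T}{A + T}, \qquad
  \mathrm{GC\text{-}skew} = \frac{G - C}{G + C}.$$

Ambiguous bases (`N`) are tallied separately and excluded from every
denominator. Values are held at full precision internally; rounding (2
decimals for percentages, 5 for skews) happens only in report writers.
For the PCG aggregate, minus-strand genes contribute their
reverse-complemented (coding-strand) sequence, matching standard
practice for composition tables; bases inside gene overlaps count once
per gene, so the aggregate equals the sum of per-gene profiles.

## Codon usage under the vertebrate mitochondrial code

Translation uses NCBI table 2 (`TGA` = Trp, `ATA` = Met, `AGA`/`AGG` =
stop), taken from the Biostrings genetic-code registry. Relative
synonymous codon usage for codon $c$ in a family of $k$ synonyms is
$\mathrm{RSCU}(c) = k\,n_c / \sum_{c'} n_{c'}$; family values sum to $k$,
and stop codons are excluded from both RSCU and amino-acid frequencies
(they are not synonymous choices for an amino acid). Codons containing
`N` are skipped and counted as ambiguous.

Start codons are classified `canonical-ATN` (any `ATN`, reflecting how
these genes actually initiate), `alternative` (`TTG`/`GTG`, observed in
some primates), or `invalid`. Stops are `complete` (a stop codon of the
code), `incomplete` (a trailing `T`/`TA` remainder — completed to `TAA`
by polyadenylation in vivo, so a class rather than an error), or
`invalid`.

## Control region analysis

The control region is extracted as one wrapped sequence and all reported
positions are region-local (1..length). Motif counting defaults to
*overlapping* occurrences (every matching start position); the
non-overlapping greedy convention is available via a flag, since
published motif counts rarely state which convention they used.

Tandem-repeat detection is exact-match only, by the naive
O(n·max_unit) scan — entirely adequate at control-region scale (~1 kb)
and trivially checkable against a brute-force oracle. Reported arrays
are maximal (not extendable by a full unit), primitive (a poly-A run is
reported once with unit `A`, never again as `AA`), leftmost-phase, and
disjoint per unit: when two maximal stretches of the same unit meet with
a partial overlap, the later array is trimmed forward by whole units.
No mismatch tolerance is attempted; degenerate or diverged repeats are
out of scope.

## Pairwise comparison

Two conspecific mitogenomes deposited with different linearization
origins must first share an origin; `rotate_to_anchor()` rotates (and,
for a reverse-deposited genome, reverse-complements) both genomes to a
unique anchor sequence. Alignment is then global Needleman–Wunsch with
affine gaps (Gotoh's three-state recurrence, compiled code), default
scores `match +1, mismatch -1, gap open -4, gap extend -1`, where a
k-base gap costs `open + k*extend`. Tie-breaking is deterministic —
diagonal, then gap-in-query, then gap-in-reference — so identical inputs
always yield byte-identical output. A diagonal band (default 200 bp,
far wider than the cumulative indel offset between conspecific
mitogenomes, which is tens of bases) keeps the 16.5 kb × 16.5 kb
problem at a few megabytes and well under a second; `band = 0` computes
the full matrix, and the test suite checks banded and full results agree
and that scores match an independent aligner.

Variant calling scans alignment columns, merges adjacent gap columns
into single indel records, and *left-aligns* every indel to its lowest
equivalent reference position (the usual VCF-style normalization). The
same normalization is applied to implanted truth sets, so recovery can
be scored by exact record equality. Consequence annotation recomputes
the affected codon on the coding strand: PCG substitutions are
`synonymous` or `missense` by table-2 translation; PCG indels are
`frameshift` when their length is not a multiple of 3, `inframe`
otherwise; tRNA/rRNA variants are `rna` (never "translated"); control
region and intergenic variants are `noncoding`. A variant inside
overlapping genes (the `atp8`/`atp6` case) yields one consequence record
per covering gene.

## The synthetic genome generator

`generate_genome()` exists so every stage of the pipeline can be
validated without downloading public accessions. It realizes a layout's
lengths, strands, gaps and overlaps *exactly* (the default layout
reproduces the published coordinates verbatim, control region wrapping
included) and fills in sequence:

* PCG interiors are sampled codon-wise from non-stop codons, so genes
  start `ATG`, end `TAA` (or a valid incomplete `T`/`TA` stop for
  lengths not divisible by 3) and contain no internal stop.
* Overlap conflicts are resolved with start codons as immutable anchors
  and a repair pass for stops and internal stops. One conflict in the
  published layout is provably unresolvable: `nad4`'s start codon forces
  `nad4l`'s final codon to `TG·`, which cannot be a stop — precisely the
  situation in the real annotation, reported as a warning.
* tRNA, rRNA, control-region and spacer positions are plain background
  sequence; no tRNA secondary-structure realism is attempted.
* Background composition is drawn as an exact-count multiset *after* the
  coding regions, compensating their composition so the realized
  genome-wide A+T content lands within rounding of the target (default
  0.614, the A+T fraction reported for this genome). A/T and G/C
  balances are independently tunable to set skew targets.

`mutate_genome()` implants a configurable mix of substitutions,
insertions and deletions (defaults 30/4/9 — the scale of the 43 variant
positions reported between conspecific douc mitogenomes), with at least
`min_spacing` bp (default 50) between events and a buffer from the
linearization origin so a linear alignment sees every event in context.
Truth records use the same normalized representation as the caller.
Seeds are mandatory; every generator output is a pure function of
(layout, parameters, seed).

What passing these tests shows — and what it does not: perfect
precision/recall on well-spaced implanted events demonstrates that the
alignment, merging, normalization and bookkeeping are correct, not that
real-data recovery is perfect. Real comparisons face clustered variants,
repeat-mediated ambiguity, and assembly error, none of which the
generator emulates (by design: no transition/transversion bias, rate
heterogeneity, or repeat expansion dynamics).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `at_target` | 0.614 | fraction | genome-wide A+T of the reference douc mitogenome |
| `a_balance`, `g_balance` | 0.5 | fraction | background A/(A+T), G/(G+C); 0.5 = zero skew |
| `match/mismatch` | +1/−1 | score | standard nucleotide scoring for near-identical genomes |
| `gap_open/gap_extend` | −4/−1 | score | favors one multi-base indel over scattered gaps |
| `band` | 200 | bp | ≫ cumulative indel offset between conspecific genomes |
| `min_spacing` | 50 | bp | separates implanted events beyond gap-merging reach |
| `max_indel` | 3 | bp | small indels, the class seen between conspecific genomes |
| `window/step` | 500/250 | bp | sliding-window skew resolution |
| motifs | TATAA, AATAAT | — | short A+T-rich signals scanned in primate control regions |

## Numerical and degenerate-input choices

Skews with a zero denominator are `NA`, empty or all-`N` regions are
errors, and a zero-total RSCU family is all-zero rather than `NaN`.
Features entirely contained in another feature are paired by start order
with a warning rather than rejected. Annotations are kept sorted by the
start of the non-wrapping span, which is genome order on the circle
linearized at the origin. `feature_length`, gap normalization and
extraction are all exact integer arithmetic; the only stochastic
components are the generator and mutation plans, both seeded.

## Validation problem sizes

The shipped test suite exercises: the full 38-row reference feature
table (every printed length and gap value); conservation on 100
randomized circular layouts; composition and skew against brute-force
tallies on 1,000 random sequences plus complement-negation symmetry;
RSCU family sums on random counts; motif scanning against a
position-by-position oracle on 1,000 random cases; tandem repeats
against a direct-enumeration oracle on 200 random strings; alignment
scores against an independent implementation on random pairs up to 2 kb;
and end-to-end recovery (precision = recall = 1, plus exact
reconstruction of the query from called variants) on full-size 16,541 bp
genome pairs across 100 mutation seeds.

## Known limitations

* Annotation is an input: no gene finding, and no validation that an
  annotation is biologically sensible beyond coordinate checks.
* Single-molecule only; no multi-record FASTA or nuclear contigs.
* Exact tandem repeats only; diverged repeat arrays are invisible.
* The comparison stage assumes near-identical genomes; at larger
  evolutionary distances a banded global alignment with these defaults
  is not an appropriate tool.
* Reproducing published cross-accession difference counts requires the
  corresponding public records as input; see the README for the recipe.
  The package's own validation rests on synthetic truth sets instead.
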