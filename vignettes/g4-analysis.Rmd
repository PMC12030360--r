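---
title: "Methods: genome-wide G-quadruplex detection and strand-aware regulatory statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide G-quadruplex detection and strand-aware regulatory statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4scape)
```

## The detection model

G-quadruplexes fold in runs of guanines; the propensity of a locus is
approximated by a run-length score. Every base in a maximal run of $k$
consecutive G's scores $+\min(k, c)$ with cap $c = 4$ (a run of four
guanines already supports a stacked tetrad core, so longer runs saturate);
C-run bases score $-\min(k, c)$, capturing G tracts on the reverse strand;
A, T and N score 0, and N additionally breaks runs. A window of width
$w = 25$ bp slides one base at a time and the arithmetic mean of the
per-base scores is compared with a threshold $t = 1.2$: windows with
mean $\ge t$ are G-rich candidates reported on the "+" strand, windows
with mean $\le -t$ C-rich candidates on the "−" strand. The comparison is
inclusive; an inclusive boundary is a deterministic convention that makes
counts reproducible.

Selected windows of the same sign that overlap or are adjacent merge into
one candidate. Each candidate is then refined: an end falling inside a
G run (positive candidates) or C run (negative) is extended to the
complete run, and terminal zero-scoring bases are trimmed. The reported
score is the mean base score over the refined interval — it can differ
from the selecting window means, so no post-hoc threshold is re-applied —
and the most extreme selected window mean is kept as a secondary column.
The scoring rule is antisymmetric under reverse complement
(`base_scores(revcomp(s)) = reverse(-base_scores(s))`), which the test
suite asserts as a property together with exact agreement with a naive
re-scan that recomputes every window mean directly.

Two post-detection cleaning steps are applied by default and are exposed
as flags recorded in the run manifest: hits whose refined interval
contains an N are dropped (an undetermined base inside a reported
quadruplex makes the call unreliable), and duplicated
(start, end, strand) intervals are removed. Lowercase (soft-masked) bases
are scanned like uppercase by default; `mask_lowercase = TRUE` treats
them as N instead.

## Coordinates

Intervals are held as `GRanges`, i.e. 1-based closed, the native
convention of the Bioconductor stack this package is built on. File
exchange follows each format's own convention: GFF3 is read as 1-based
inclusive, BED and bedGraph are written 0-based half-open.

## Regions and strand context

From GFF3 the package derives, per gene: the gene body; exon, CDS and UTR
unions over the gene's transcripts; introns (per-transcript span minus
exons, unioned per gene); `promoterN` for N ∈ {2000, 1500, 1000, 500};
and `TSS500`. "Upstream" is taken relative to gene orientation — the only
biologically coherent reading of a promoter — so for a "+" gene
`promoterN` is the N bp left of the gene start and for a "−" gene the N
bp right of the gene end. The TSS is the first base of the gene feature
in gene orientation; `TSS500` spans 250 bp on each side of it, with the
TSS base itself in the downstream half (the `GenomicRanges::promoters()`
convention). Gene-level regions are used rather than per-transcript ones
because the downstream statistics are per-gene and isoform resolution is
out of scope. Regions are clipped to the contig; regions clipped away
entirely (a gene at a contig edge) are dropped, logged, and excluded from
density denominators.

A hit counts in a region when they overlap by at least one base; a hit
may therefore count in several region classes and several genes. Its
strand context relative to a host gene is **coding** when the hit's
G-rich strand equals the gene strand and **template** otherwise; since a
hit carries exactly one strand, per-gene coding and template counts
always partition the double-strand count.

Two density denominators are computed because either reading of
"density of a region class" is defensible: the default **union**
denominator divides distinct hit counts by the total bp of the interval
union of the class (no double-counted bp where promoters of neighbouring
genes overlap), while **per_gene** sums each gene's own span and counts a
hit once per overlapped gene. Both tables are written by the pipeline;
tests pin down their agreement on non-overlapping fixtures. Coding and
template contexts share the double-strand span: both strands of a region
have identical exposure by construction.

## Strand bias, classification, correlations

The strand fold difference (G4SDF) of a region set is
$\max(d_c, d_t) / \min(d_c, d_t)$ with the dominant strand recorded; ties
give 1, one zero side gives an infinite, flagged fold, and zero/zero is
undefined and flagged. Significance uses the exact two-sided binomial
test of the coding count among all stranded hits at $p = 1/2$ — under
equal strand exposure this is the natural null; the choice of test is a
package decision, made because counts under equal exposure need no
variance model.

Gene classification bins every annotated gene (zero-count genes included)
by its hit count in a class and reports genes whose count strictly
exceeds a cutoff — 10 for promoters, 5 for TSS windows by default — with
proportions over the full gene universe. Chromosome-level association
uses Pearson correlation (`stats::cor.test`) between per-chromosome G4
density and GC content or gene/tandem-repeat/TE counts per kbp; at least
three chromosomes are required and zero-variance tracks are flagged
rather than tested. Windowed tracks assign each hit to the window
containing its start coordinate so that tiling windows conserve the total
count.

## DEG overlay

The package consumes a differential-expression results table rather than
re-estimating anything upstream: genes are `up` when
`log2FoldChange >= 1` and `padj <= 0.05`, `down` mirrored, `ns`
otherwise, with missing `padj` treated as not significant (that is what
an NA from independent filtering means operationally). Group densities
restrict all denominators to the listed genes' regions. Selection by
strand fold is per-gene with the strict inequality `fold > 3` by default;
genes with hits on only one strand are selected with an infinite,
flagged fold, and zero/zero genes are excluded. Whether such a selection
should be per-gene or pooled over the group is genuinely ambiguous, so
per-gene is the default and a `pooled` flag computes the group-level fold
instead with all-or-none selection.

## What the synthetic generator emulates — and what it does not

`synth_generate()` builds non-overlapping genes on both strands in fixed
slots (3 kb upstream space, 2 kb downstream) on a background sampled at a
target GC fraction. Two constraints make recovery tests exact rather than
statistical: the background is first stripped of any G/C run of length
three or more, and then — because the run rule alone does not bound
window means (a `GGA`-repeat window reaches mean 1.28) — re-scanned and
mutated until no window reaches the detection threshold. Every planted
motif is written with 13 zero-scoring flanking bases on each side, which
confines all selecting windows to the motif so the refined hit equals the
planted interval exactly, with the motif's own score.

The default parameters are the study conditions the statistics are
exercised under: total promoter2000 density 0.54/kbp with a 2:1 coding
bias, TSS500 density 1.00/kbp with balanced strands, CDS planted at a
2.45:1 coding:template ratio, and 25-gene up/down groups carrying 3:1
template- and coding-dominant TSS500 ratios (planted counts are rounded
to integers, so recovered folds sit near, not exactly at, 3). The genome
size — 3 chromosomes × 60 genes ≈ 1.4 Mb, roughly a thousand planted
motifs — keeps the full suite in tens of seconds while leaving ≥ 50
planted hits behind each recovered density and ≥ 100 behind each group
ratio. Bulk TSS500 motifs are planted only in the downstream half of the
window and promoter motifs only upstream of it, so the promoter and TSS
recovery targets do not contaminate each other; burden-rich and DEG genes
use the full TSS window, which is why their TSS hits also appear in their
own promoter counts — the truth tables account for this by direct
interval arithmetic on the planted coordinates.

What the generator does **not** emulate: real base composition (the
background is near-iid with runs capped, where real genomes have isochore
and repeat structure), G4s of heterogeneous length and score (every plant
is the same 25-mer), overlapping genes and isoforms, tandem-repeat or TE
tracks, and any coupling between expression values and G4 placement
beyond the planted group ratios. Passing recovery tests therefore
demonstrates that the measurement machinery is unbiased on clean signal;
it says nothing about detection completeness on real sequence, where the
threshold trades sensitivity against specificity.

`synth_perturb()` mutates the central G of a chosen fraction of planted
motifs to T (C to A on reverse-strand plants), which breaks the central
run and lowers the refined score from 37/25 to 32/25 — still above the
default threshold, so it degrades scores without necessarily removing
hits; hit counts are non-increasing in the mutated fraction.

## Numerical choices and degenerate inputs

Densities are `count × 1000 / span` and are kept at full precision
internally; file reports round to 2 decimals. Zero spans, zero-variance
correlation tracks, one-sided and zero/zero strand folds, and empty DEG
lists all return flagged records or warnings rather than errors. Empty
FASTA files, duplicated sequence IDs, duplicated DEG gene IDs, missing
strands on genes and unresolvable GFF parents are rejected loudly.
Sequences shorter than the window produce no windows, with a message.
The pipeline writes no timestamps, so a rerun with identical inputs and
parameters reproduces byte-identical outputs, verified by the manifest
checksums.

## Limitations

The score is a propensity, not a structure determination; no folding
thermodynamics, cation dependence or experimental validation is modelled.
Promoter definitions are annotation-driven and gene-level — alternative
TSSs are invisible. The strand-bias test assumes hits are independent
draws, which long merged hits spanning region boundaries can violate
slightly. Genome-scale reproduction of published chromosome tables
requires the corresponding assembly and annotation as inputs; the package
ships only the printed per-chromosome summary for arithmetic checks, and
the unspecified post-detection "cleaning" used by any given published
count means small count shifts are expected when rescanning a real
assembly with different cleaning flags.
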