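---
title: "Models and methods: TE insertion context, hybrid splicing, and piRNA strand bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: TE insertion context, hybrid splicing, and piRNA strand bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(terewire)
library(dplyr)
```

`terewire` measures two linked phenomena in somatic cell genomes: how
intronic LTR-retrotransposon insertions rewire host isoforms through
hybrid splicing, and how the strand composition of TE-mapping piRNAs
tracks the capacity to silence those elements. This vignette explains
the models and procedures, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## Coordinates and containers

Every interval in the package is 0-based half-open with strand in
`{+, -, *}`. The 1-based inclusive conventions of GFF3, RepeatMasker
`.out` and SAM are converted at the I/O boundary and nowhere else, so
off-by-one reasoning is confined to the readers and writers (which are
round-trip tested). Gene models, transcripts, insertions, alignments and
blocks are all plain tibbles, one row per exon / insertion / read /
block, so every stage composes with ordinary dplyr verbs.

## Insertion classification

An insertion is **exonic** if it overlaps at least 1 bp of any exon of
any isoform of an overlapping gene, **intronic** if it falls inside a
gene span without touching an exon, and **intergenic** otherwise. The
categories are mutually exclusive with exonic taking priority, which
keeps composition fractions summing to one without isoform-level
ambiguity. Orientation is **forward** when the insertion strand equals
the host-gene strand — the configuration competent for hybrid splicing,
since only then does the element's promoter fire in the host's
direction — and intergenic insertions get `not-applicable` rather than a
strand guess.

Intron ordinals (1-based, in transcription order) are computed on the
isoform with the most exons, ties broken by transcript id. Annotation
sources differ in which isoform they consider primary and the choice
shifts ordinals for a minority of genes; the most-exon isoform is the
most granular and therefore the most conservative about calling
something "first intron". When several genes overlap an insertion, the
primary call goes to the gene whose exon is hit, else to the gene with
the shortest enclosing intron (the more local context), ties broken
lexicographically — and the `ambiguous` flag is always set so downstream
analyses can drop such calls.

The distance covariate is measured from the insertion's 3′ boundary (in
gene orientation) to the 5′ boundary of the nearest downstream exon,
mirror-symmetrically for minus-strand genes; `boundary = "end"` measures
to the exon's 3′ boundary instead, since annotation practice varies on
which boundary is reported. Insertions in a terminal intron with no
annotated downstream exon get a distinguished `NA` rather than zero.

## Hybrid-splice calling

A transcript supports a hybrid event for an intronic-forward insertion
when (a) its 5′ end lies inside the insertion interval, (b) its first
splice junction donates from inside the insertion and accepts within
`acceptor_tol` of the 5′ boundary of an annotated host exon, and (c) it
runs in the host gene's direction. The 5′-end-inside-TE requirement
reflects transcription initiating within the 5′ LTR; a relaxed mode
(`require_tss_in_te = FALSE`) accepts any transcript whose first exon
overlaps the element, for degraded 5′ ends. `acceptor_tol` defaults to
5 nt to absorb long-read end wobble; with exact exon chains, tolerance 0
recovers the same events (tested). A single supporting transcript
suffices for the per-insertion verdict by default — long-read transcript
models are already collapsed isoforms, not raw reads — and the threshold
is exposed as `min_support`.

Donor discovery on TE sequence is a plain IUPAC scan for GT-type
patterns (`GTAAGT` by default; the weak copia-type `GTATGT` by pattern
swap). No donor-strength scoring model is invented: the biology the
package measures distinguishes donors by their observed splicing
outcomes, not by a motif score.

## The splicing-competence test

Distances of spliced vs unspliced intronic-forward insertions are
compared with a self-implemented two-sided Mann–Whitney *U* test:
`U = R1 − n1(n1+1)/2` with midranks. When the data are tie-free and
`n1·n2 ≤ 400`, the exact null distribution of `U` is built by
subset-sum dynamic programming over rank sums and the p-value is
`min(1, 2·min(P(U ≤ u), P(U ≥ u)))`; otherwise a normal approximation
with tie-corrected variance and a 0.5 continuity correction is used (the
common default of mainstream implementations). The exact branch is
tested against brute-force enumeration of all rank assignments; the
asymptotic branch's exact rejection probability at `n = 30 + 30`,
`α = 0.05` is 0.048, and a 2,000-replicate null simulation in the test
suite confirms the empirical rate sits in [0.04, 0.06].

## piRNA quantification

Reads are size-filtered to the inclusive 20–35 nt piRNA range, counted
once each (primary alignments only; upstream mapping is assumed to have
collapsed multi-mappers to one site), and split by SAM flag into sense
(forward) and antisense (reverse) per TE consensus. CPM uses
`1e6 · count / denominator` with the library size — total reads retained
after genome mapping and size filtering — as the default denominator, so
per-family CPMs sum to 1e6 exactly when the denominator is the counted
total; a consensus-mapped denominator is available where a library-size
denominator is not meaningful. Sense fraction is `100·s/(s+a)`, left
`NA` when a family has no reads rather than coerced to zero, because "no
data" and "perfectly antisense" are different facts. The sense-biased
label uses a 50% threshold (exposed as a parameter): above it, the
majority of a family's piRNAs match the mRNA strand and cannot base-pair
with it, which is the mechanistically meaningful boundary.

## Genome metrics

Occupancy merges (unions) a family's intervals before summing, so
fragmented annotations do not double-count. Enrichment between
assemblies is provided in two first-class modes — ratio of occupancy
fractions, and ratio of full-length copy counts (full-length meaning
`length ≥ min_len` and/or `≥ min_frac` of the consensus, boundaries
inclusive) — because the two conventions answer different questions and
both appear in practice; a zero baseline yields a flagged `Inf`, not an
exception. Syntenic fraction of a region is the union of
(syntenic-class) alignment blocks clipped to the region, as a percentage
of the region; syntenic and non-syntenic percentages sum to 100 exactly
by construction.

Presence calls use junction-spanning reads: a read supports a junction
when it covers `min_overhang` (default 10 nt) on both sides of the
insertion boundary, and an insertion is `preexisting` when **both**
junctions have `min_support` reads — the stricter reading of
"reads spanning the TE and its flanking sequences" — with a one-junction
mode for truncated elements.

## PWM scanning with exact calibration

Motif scores are `Σ log2(p_col(base)/bg(base))`. P-values are exact tail
probabilities of the score of a random background word, computed by
dynamic-programming convolution over the score distribution discretized
at `step` bits (default 1e-3, giving a score error bound of
`w·step/2`). The scan and the lookup table share the same discretized
score matrix, so a looked-up p-value is exactly the discretized score's
tail probability; for widths ≤ 6 the DP distribution is tested to equal
brute-force enumeration of all `4^w` words. An exact-match heptamer PWM
against a uniform background gives the closed-form `4⁻⁷ ≈ 6.1e-5` per
window per strand. The background defaults to 0-order uniform and can be
estimated from the scanned sequence or supplied; zero background
probability for an observed base is an error directing the user to
pseudocounts (default 1e-3 per cell).

## Metaprofiles and random controls

Metaprofiles are site-centered (reference-point): the track is resampled
into `2·flank/bin` bins around each site, missing positions are zero,
rows of minus-strand sites are flipped, and the mean profile is the
column mean. Multi-sample profiles are averaged arithmetically after
per-sample normalization. A scale-regions reading of fixed-size windows
is functionally the same computation on these inputs, which is why the
site-centered form is the one implemented. Control windows are sampled
uniformly over chromosome lengths (chromosome chosen proportional to its
placeable span) without overlap checking, matching the behaviour of
standard window-shuffling tools; the seed is mandatory and recorded.

## The synthetic-data generator

`simulate_te_dataset()` emits, from a single seed, a two-haplotype
annotation set (~150 genes and 150 insertions per haplotype by default:
10 exonic, 55 intronic-forward, 35 intronic-reverse, 50 intergenic —
about 300 insertions in total), canonical plus hybrid transcript models,
small-RNA alignments with per-family sense fractions, an accessibility
track with a peak upstream of every insertion, AT-rich-style motif
arrays holding each insertion at a Beta(3,3) relative position,
junction-spanning genomic reads at 10×, and haplotype alignment blocks
with three planted non-syntenic segments in a designated cluster-like
region. Every emitted record traces to a truth entry, and identical
seeds give byte-identical bundles (tested on file checksums).

The splicing model is the scientific core of the generator: distances to
the downstream exon are drawn as `log10 d ~ N(3.675, 0.475)` truncated
to `[10^2.3, 10^4.6]`, and an insertion splices with probability
`plogis(0.5 − 4.2·(log10 d − 3.725))`. These constants were calibrated
once, by simulation, so the unspliced/spliced median ratio is ≈3.6 and
about 60% of forward intronic insertions splice — the regime reported
for the biological system this emulates — and they are not revisited.
Element geometry defaults to a 7,546-nt element with a 405-nt LTR and
the donor 43 nt past the LTR end (the LTR length itself is a free
parameter; only the donor offset is anchored). Host genes receive
insertions with probability proportional to expression
(`expression$bias`), introns 1–3 are preferred at 55/30/15%, and
reverse-intronic insertions draw distances from the same law without the
logistic response.

What the generator does **not** emulate: sequence divergence and nested
insertions, read errors (perfect reads only), multi-mapping ambiguity,
isoform diversity beyond one canonical transcript per gene, and
selection. Passing tests on this data therefore demonstrate the
*operations* are correct — coordinate arithmetic, event logic, counting,
calibration — not that the pipeline is robust to noisy annotation or
degraded long reads.

## Problem sizes and numerical choices

The test suite and acceptance script run the default ~300-insertion
bundle, a 220-intF bundle for hybrid precision/recall (≥100 planted
hybrid and ≥100 canonical transcripts), 200 replicates of the distance
model at n = 110, a 2,000-replicate Mann–Whitney null, 10⁴ reads per
family for sense-fraction recovery, and PWM enumeration up to width 6 —
sizes chosen so the full suite completes in about a minute while keeping
every check's sampling error well below its assertion margin. Interval
unions use a sorted-scan implementation (validated against
`GenomicRanges::reduce`) so per-gene operations stay cheap; coverage
extraction uses IRanges run-length encodings. Degenerate inputs follow a
consistent policy: empty interval sets give zero occupancy, empty read
sets give zero coverage and `NA` sense fractions, zero baselines give
flagged `Inf` enrichment, and empty groups or regions are errors.

## Limitations

Classification trusts the annotation: unannotated isoforms shift intron
ordinals and downstream distances. Event calling requires the acceptor
to match an annotated exon boundary, so hybrid splicing into cryptic
acceptors is not called. The per-insertion verdict has no read-depth
model — one supporting transcript model suffices — and the package does
not model the competition between splicing and premature
polyadenylation that plausibly generates the distance dependence it
measures; it only quantifies that dependence.
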