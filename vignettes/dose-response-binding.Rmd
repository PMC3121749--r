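---
title: "Classifying dose-response transcription-factor binding across three signaling conditions"
author: "ChIPmodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying dose-response binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Morphogen pathways such as Nodal/Activin act through graded signaling: the
same transcriptional effector (phosphorylated Smad2) occupies different
genomic sites depending on the signaling level, and target genes respond to
specific thresholds rather than uniformly. Given ChIP-Seq peak calls from
three ordered conditions — LOW (pathway inhibited), MID (vehicle control)
and HIGH (ligand stimulated) — the analysis asks, per binding site and per
gene: does occupancy follow the gradient, is it confined to one end of it,
or is it unchanged? And do those binding behaviors line up with
differential expression and with the underlying Smad-binding DNA elements
(SBE: CAGA, canonically CAGAC)?

`ChIPmodes` implements this analysis as a reusable pipeline: cross-condition
peak merging and Venn partitioning, genomic-feature annotation, site-gene
association, dose-response mode classification, expression integration, and
motif statistics — together with a synthetic-data generator that plants
known binding modes, motifs and expression effects so every stage can be
validated without external data.

## Data model

Peaks of one condition form a `PeakSet`: a disjoint, sorted `GRanges` with
raw tag counts and depth-normalized enrichments
(`raw_tags * referenceDepth / libraryDepth`, reference depth 10^7 — the
floor of the typical 10-13 million-tag library). Depth normalization makes
peak heights comparable across the three libraries; input-DNA correction is
assumed to have happened upstream in the peak caller.

`mergeUnion()` single-links all peaks with at least 1 bp of overlap across
conditions into *union intervals* — the atomic unit of everything
downstream. Each union interval carries a per-condition enrichment triple
(the maximum enrichment among that condition's contributing peaks, 0 when
the condition contributed none) and a presence set, which drives the
three-set Venn partition. Abutting intervals are never merged; there is no
reciprocal-overlap requirement, matching the coordinate-overlap definition
of a shared site.

Internally all coordinates are 1-based closed, the native convention of
`GRanges`; 0-based half-open coordinates exist only in BED files and are
converted at the I/O boundary. Footprints round-trip exactly, and the
half-open boundary semantics of BED (adjacent features share no base) are
preserved by merging with `min.gapwidth = 0`.

## The mode classifier

The heart of the package is `classifySites()`. Enrichment triples
`(e_L, e_M, e_H)` are first floored at a pseudocount (default 1): a
condition in which the peak caller saw nothing is treated as background,
not as zero, so ratios stay finite. With fold threshold `f = 1.5` (the
high-confidence binding-change cutoff) and responsive threshold `r = 1.25`
(the minimal variation considered real), the first matching rule wins:

1. **INVARIANT** — `max/min < r`; occupancy does not vary appreciably.
2. **GRADED** — occupancy monotone increasing with signaling
   (`e_H >= e_M >= e_L`), full span at least `f`, and both steps at least
   `r`. The requirement that the MID condition sits distinctly above LOW
   (`e_M/e_L >= r`) encodes the defining *moderate intermediate response*:
   without it, a site bound only under high signaling (background LOW and
   MID) would satisfy the weak monotonicity `e_H >= e_M >= e_L` and be
   miscalled graded.
3. **HIGH_DOMINANT** — `e_H / max(e_M, e_L) >= f`.
4. **LOW_DOMINANT** — `e_L / max(e_M, e_H) >= f`.
5. **COMPLEX** otherwise. A monotone-*decreasing* profile short of LOW
   dominance lands here deliberately: the graded mode is defined only in
   the increasing direction.

Classification is total, deterministic and invariant to uniform scaling
above the floor. Sites enter classification only if their raw tag count
strictly exceeds 12 in at least one condition — the high-confidence floor.

Genes collect every union interval whose footprint intersects the
transcript extended by 50 kb on both sides (one-to-many in both
directions). A gene's mode is `NONE` without a responsive
(non-INVARIANT) site, the shared mode when all responsive sites agree, and
`MULTIMODAL` when they disagree — e.g. a low-dominant promoter site next
to a graded intronic enhancer.

```{r example}
library(ChIPmodes)
classifySites(rbind(c(0, 51, 107),    # graded
                    c(80,  0,   0),   # low-signaling dominant
                    c(0,   0,  90),   # high-signaling dominant
                    c(50, 50,  50)))  # invariant
```

## Annotation and profiles

Sites are annotated at their midpoint (summits can disagree across
conditions; the midpoint is the single condition-independent
representative). Nine categories are resolved by fixed priority:
`PROMOTER > UTR5 > UTR3 > EXON > INTRON > TTS_PROX > DISTAL5 > DISTAL3 >
DESERT`, with the promoter and TTS windows at ±2 kb (matching the ±2 kb
TSS profile view) and the distal limit at 50 kb (matching the association
window). UTRs require CDS bounds; exonic positions of non-coding models
are `EXON`. Equidistant-TSS ties break toward the lexicographically
smaller gene id — arbitrary but deterministic. The TSS profile bins
strand-oriented offsets to the nearest TSS in 50 bp bins over ±2 kb;
out-of-window sites are reported as a remainder so every site is accounted
for.

## Expression integration

Expression input is a per-gene table of log2 intensities per condition,
assumed normalized. A contrast counts as changed when its linear fold
change strictly exceeds 1.5 (or falls below 1/1.5), yielding
high-specific, low-specific, co-regulated and unchanged classes. A gene
shows *differential binding* when any of: its floored summed enrichment
changes more than 1.5-fold between two conditions; its per-condition site
counts differ; or the set of site footprints present differs (a change of
binding location at equal totals — rendered as a symmetric-difference test
because no formal definition exists). `deBindingFraction()` reports the
concordance between regulated genes and differential binding with both the
raw and the matched denominator, since the right denominator is genuinely
ambiguous.

The binding-vs-expression trend ranks genes by MID log2 expression above a
cutoff of 5.5 (excluding non-expressed genes and dead probes), takes each
gene's largest associated peak per condition — explicitly allowing the
largest peaks of different conditions to sit at different coordinates —
normalizes by the mean MID enrichment, and applies an unweighted 500-gene
moving average. The curve is invariant to uniform enrichment rescaling.

## Motif statistics

Three layers, all counting both strands:

* **Literal profiles** (`positionalProfile()`): occurrences of CAGA/CAGAC
  in 100 bp bins around site centers, against the same counting at 10,000
  random genome locations (`randomBackgroundProfile()`). Occurrences per
  region per bin is the primary statistic; a regions-with-occurrence mode
  is available because the two readings of "frequency" differ. The flank
  defaults to 1 kb on each side.
* **Exhaustive k-mer center enrichment** (`kmerCenterEnrichment()`):
  every k-mer (k = 6 or 8, canonicalized by strand) occurring in the
  ±25 bp center windows is tested for center enrichment against its own
  per-position rate in the flanks (one-sided binomial tail), with
  Benjamini-Hochberg control at 0.01; k-mers not enriched at the center
  are excluded. This replaces black-box de novo discovery with a fully
  specified computation answering the same question. The top-1000-peaks
  variant truncates regions by maximal enrichment before counting.
* **PWM co-motifs** (`comotifEnrichment()`): for each PWM the exact
  log-odds score distribution under the background is computed by
  positionwise convolution on a discretized grid (step at most 1e-3 of the
  score range per position), giving the smallest score with tail
  probability ≤ 1e-5. The reported threshold is released by the
  worst-case accumulated rounding (half a grid step per position) so
  scanning never misses a sequence the exact computation selected; the
  match set can widen by at most the boundary mass within one grid
  tolerance. Peak-window match fractions are compared to random windows
  by one-sided Fisher tests, BH-adjusted, and ranked by peak fraction.
  The scan window is a parameter (default ±1 kb; up to ±5 kb) because
  both ranges are legitimate readings of the original co-motif analysis.

A width-`w` PWM at tail probability `p` is only meaningful when
`p >= 4^-w`: below that no sequence set can attain the tail, and the
threshold is reported as `Inf` (nothing matches) rather than silently
clamped.

## The synthetic study

The generator defines the reference conditions under which the pipeline is
validated:

* **Genome and genes**: two 10 Mb chromosomes of i.i.d. uniform sequence;
  300 non-overlapping genes of 2-10 exons (exons 150-400 bp, introns
  1.5-4 kb), laid out with 18-30 kb spacing and occasional 160 kb
  gene-free stretches so genuine gene deserts (> 50 kb from any gene)
  exist. A contiguous 40% of genes is reserved binding-free so that
  expression-regulated genes *without* binding exist (see below).
* **Sites**: 1500, each drawing a mode from the mixture 25% graded / 35%
  low-dominant / 30% high-dominant / 10% invariant and a placement
  category from 6% promoter / 6% exon / 34% intron / 34% distal / 20%
  desert. Placement pools are derived from the same feature definitions
  the annotator uses (each category minus all higher-priority features,
  shrunk by a safety margin), so the planted category is exact by
  construction. Sites are at least 2 kb apart, so cross-condition merging
  can never fuse two distinct truth sites (maximal peak width 1 kb). The
  promoter and exon weights are deliberately small: a ±2 kb promoter
  window holds essentially one site under the 2 kb spacing, so promoter
  capacity is about one site per non-reserved gene.
* **Tag counts**: per condition, raw tags are Poisson with mean
  `mode_mean / depth_scale` at library depths of 12.0/13.0/10.0 million
  tags (LOW/MID/HIGH); a peak is emitted only when its raw count strictly
  exceeds 12 tags, the same floor the classifier uses, so background
  conditions yield no peak call at all. Poisson is this module's noise
  assumption — the original analysis states none. The per-mode means
  (graded 5/40/100, low-dominant 90/4/4, high-dominant 4/4/90, invariant
  400/400/400) keep every defining inequality at twice its classification
  threshold, which the configuration validates; the invariant mean is
  large because flatness under Poisson noise requires a small coefficient
  of variation. A test mode replaces draws by their means for exact
  assertions.
* **Motifs**: CAGAC is written at 80% of site centers on a random strand,
  flanks untouched, so the positional profile and k-mer layers see a known
  signal over a known background.
* **Expression**: baseline MID log2 is Normal(7, 1); genes within 50 kb of
  a HIGH-responsive site (graded or high-dominant) get a 2-fold HIGH
  contrast, genes near low-dominant sites a 2-fold LOW contrast, with 0.1
  log2 noise per condition. Additional regulated genes *without*
  responsive binding are planted so that 65% of regulated genes carry
  differential binding — otherwise concordance would trivially be 1 and
  the statistic untestable.

What the generator does **not** emulate: mappability and GC biases,
input-DNA structure, fragment-size effects, peak-caller artifacts,
overdispersed (non-Poisson) tag noise, correlated replicate structure, and
realistic genome composition. Passing the recovery tests therefore
demonstrates the correctness of the computations under controlled
conditions, not performance on real chromatin.

## Validation and problem sizes

The test suite asserts, among others: equality of the union merge with an
all-pairs connected-components oracle (300 peaks per condition), of gene
association with an all-pairs distance oracle, of literal scanning with a
naive sliding window, and of the PWM threshold with exhaustive enumeration
up to width 8; conservation laws (Venn segments sum to the union total,
category and mode percentages sum to 100, profile bins sum to scan totals)
across 50 random instances; recovery on the reference study (site-mode
accuracy at least 95%, gene-mode at least 90%, mixture proportions within
3 multinomial standard errors, concordance within 3 binomial standard
errors of 0.65, feature bias within the multinomial 99% interval); motif
calibration (planted central-bin frequency at least the plant rate, flat
random background, and BH-0.01 null discoveries in at most 1 of 20
motif-free genomes); and trend recovery (Spearman above 0.9 for planted
monotone binding over 2000 genes with the 500-gene window).

The bundled pipeline configuration runs the synthetic study at its default
scale (two 10 Mb chromosomes, 300 genes, 1500 sites) in about a minute;
its trend stage uses a 100-gene window because a 300-gene study cannot
support the 500-gene default, which is exercised separately at 2000 genes.

## Known limitations

* The mode taxonomy is threshold-based, not model-based: no count-model
  p-values or dispersion estimation (out of scope by design); borderline
  triples near `r` or `f` flip categories discontinuously.
* Gene association is purely positional (±50 kb); no enhancer-promoter
  contact information.
* The k-mer null assumes flank composition represents the center's
  background; on real genomes, centered composition biases (e.g. GC at
  promoters) would inflate enrichment and a composition-matched background
  would be needed.
* The PWM background is 0-order (uniform by default, or estimated from
  the genome with `baseComposition()`); higher-order backgrounds are not
  implemented.
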