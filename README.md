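# ChIPmodes

Dose-response binding-mode analysis for transcription-factor ChIP-Seq
across three ordered signaling conditions.

Morphogen pathways such as Nodal/Activin regulate their targets in a
graded fashion: the phosphorylated effector (pSmad2) occupies different
genomic sites at different signaling levels, and target genes respond at
specific thresholds. Given peak calls from a LOW (inhibitor), MID
(vehicle control) and HIGH (ligand) condition, `ChIPmodes` answers, per
binding site and per gene, *how* occupancy depends on the signaling dose,
and connects the answer to differential expression and to Smad-binding
DNA elements (SBE: CAGA / CAGAC).

The pipeline:

* **Union and Venn** — peaks of the three conditions are single-linkage
  merged on ≥ 1 bp coordinate overlap into *union intervals*, each
  carrying a per-condition normalized enrichment triple
  (`enrichment = raw_tags × 10⁷ / library_depth`); the presence sets give
  the three-set Venn partition of binding.
* **Mode classification** — with pseudocount-floored triples
  `(e_L, e_M, e_H)`, fold threshold `f = 1.5` and responsive threshold
  `r = 1.25`, rules in order: **invariant** (`max/min < r`), **graded**
  (`e_H ≥ e_M ≥ e_L`, `e_H/e_L ≥ f`, both steps ≥ `r`),
  **high-dominant** (`e_H/max(e_M, e_L) ≥ f`), **low-dominant**
  (`e_L/max(e_M, e_H) ≥ f`), else **complex**. Sites need > 12 raw tags
  in at least one condition. Genes collect sites within ±50 kb of the
  transcript; disagreeing responsive sites make a gene **multimodal**.
* **Annotation** — nine priority-resolved feature categories
  (promoter ±2 kb, UTRs, exon, intron, TTS ±2 kb, distal ≤ 50 kb,
  desert), plus a 50 bp-binned TSS-proximal profile over ±2 kb.
* **Expression integration** — regulated-gene classes at a strict
  1.5-fold cutoff, binding-change concordance, and the 500-gene
  moving-average trend of largest-peak binding along the expression
  ranking (cutoff 5.5).
* **Motif statistics** — CAGA/CAGAC positional profiles in 100 bp bins
  against 10,000 random genome locations; exhaustive 6/8-mer
  center-vs-flank enrichment with BH control; PWM co-motif scans with
  exact score-distribution thresholds (`P(score ≥ t) ≤ 10⁻⁵` by
  positionwise convolution).
* **Synthetic study** — a generator that plants binding modes, motifs and
  coupled expression with a truth manifest, so every stage is testable
  offline.

## Worked example

```r
library(ChIPmodes)

## enrichment triples (LOW, MID, HIGH) -> dose-response modes
classifySites(rbind(c(0, 51, 107),   # background LOW, 51 MID, 107 HIGH
                    c(80,  0,   0),
                    c(0,   0,  90),
                    c(50, 50,  50)))
#> [1] "GRADED"        "LOW_DOMINANT"  "HIGH_DOMINANT" "INVARIANT"

## a small synthetic study, end to end
sc   <- simulationConfig(seed = 7, nChroms = 1L, chromLength = 4000000L,
                         nGenes = 40L, nSites = 150L)
sim  <- simulateGenome(sc)
land <- simulatePeakLandscape(sc, sim$genome, sim$genes)
u    <- mergeUnion(land$peaksets$LOW, land$peaksets$MID,
                   land$peaksets$HIGH)
vennPartition(u, land$peaksets)
#> Venn partition of 150 union binding sites
#>       segment count percent
#>           LOW    57   38.00
#>           MID     0    0.00
#>          HIGH    35   23.33
#>       LOW,MID     0    0.00
#>      LOW,HIGH     1    0.67
#>      MID,HIGH    39   26.00
#>  LOW,MID,HIGH    18   12.00
#> per-condition union totals: LOW=76 MID=57 HIGH=93
#> pre-merge input peak totals: LOW=76 MID=57 HIGH=93

gb  <- associateGenes(u, sim$genes)
idx <- S4Vectors::metadata(gb)$siteIndex
sm  <- classifySites(enrichmentTriple(u[idx]))
modeStatistics(sm, classifyGenes(gb, sm))
#> Site modes (percent of 132 responsive sites):
#>           mode count  percent
#>         GRADED    39 29.54545
#>   LOW_DOMINANT    57 43.18182
#>  HIGH_DOMINANT    36 27.27273
#>      INVARIANT    18       NA
#>        COMPLEX     0  0.00000
#> ...

## recovery against the planted truth
mean(sm[matchTruthSites(u[idx], land$truth)] == land$truth$mode)
#> [1] 1
```

The Venn segments show what the merge found: 57 LOW-only, 39 MID∩HIGH and
18 triple-overlap sites out of 150 — peaks appear and disappear as the
signaling level changes, exactly the planted behavior. The mode table then
names the per-site behavior (here 29.5% graded, 43.2% low-dominant and
27.3% high-dominant of 132 responsive sites), and the final line checks
the calls against the generator's truth manifest.

A configuration-driven run of all stages writes TSV tables and a manifest:

```r
runPipeline(pipelineConfig(seed = 1, outdir = "out"), "all")
```

or from a shell via the thin wrapper
`Rscript inst/scripts/chipmodes.R all --seed 1 --outdir out`.

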