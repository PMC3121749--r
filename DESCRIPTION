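Package: ChIPmodes
Title: Dose-Response Binding Mode Classification for Multi-Condition ChIP-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of transcription-factor ChIP-Seq occupancy across three
    ordered signaling conditions (LOW, MID, HIGH). Merges per-condition peak
    calls into cross-condition union binding sites and computes their Venn
    partition, annotates sites to genomic features and TSS-proximal profiles,
    associates sites with genes within a +/-50 kb window, classifies sites and
    genes into dose-response binding modes (graded, low-signaling dominant,
    high-signaling dominant, invariant, complex, multimodal), integrates
    binding with differential expression (concordance and a moving-average
    binding-versus-expression trend), and profiles Smad-binding-element
    (CAGA/CAGAC) and de novo k-mer/PWM motif enrichment around peak centers
    with exact PWM score-distribution thresholds. A synthetic-data generator
    plants known binding modes, motifs and expression effects so that every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
biocViews: ChIPSeq, Epigenetics, GeneRegulation, MotifAnnotation,
    Transcription, Sequencing
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
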