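## Fixture builders and independent oracles shared across the suite.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
  library(S4Vectors)
})

## Shared seqlevels keep GRanges combination quiet across fixtures.
.FIX_SEQLEVELS <- c("chr1", "chr2", "chr9")

## A PeakSet from parallel vectors, defaulting to identity depth scaling.
makePeakSet <- function(cond, start, end, tags, chrom = "chr1",
                        depth = 1e7, ref = 1e7, summit = NULL) {
  gr <- GRanges(chrom, IRanges(start, end), raw_tags = tags)
  GenomeInfoDb::seqlevels(gr) <- union(GenomeInfoDb::seqlevels(gr),
                                       .FIX_SEQLEVELS)
  if (!is.null(summit)) gr$summit <- summit
  PeakSet(gr, cond, libraryDepth = depth, referenceDepth = ref)
}

## Random disjoint peaks for one condition on [1, len].
randomPeakSet <- function(cond, n, len = 1e6, chrom = "chr1") {
  s <- sort(sample.int(len - 300L, n))
  w <- sample(50:250, n, replace = TRUE)
  makePeakSet(cond, s, pmin(s + w, len), sample(13:200, n, replace = TRUE),
              chrom = chrom)
}

## A single-transcript gene with evenly spaced exons.
makeGene <- function(id, chrom, start, end, strand = "+", nExons = 2,
                     cds = TRUE) {
  bounds <- round(seq(start, end + 1, length.out = 2 * nExons))
  es <- bounds[seq(1, 2 * nExons, by = 2)]
  ee <- bounds[seq(2, 2 * nExons, by = 2)] - 1L
  ee[nExons] <- end
  gr <- GRanges(chrom, IRanges(start, end), strand = strand)
  GenomeInfoDb::seqlevels(gr) <- union(GenomeInfoDb::seqlevels(gr),
                                       .FIX_SEQLEVELS)
  gr$gene_id <- id
  gr$exons <- IRangesList(IRanges(es, ee))
  gr$cds_start <- if (cds) as.integer(es[1]) else NA_integer_
  gr$cds_end <- if (cds) as.integer(ee[nExons]) else NA_integer_
  gr
}

## O(n^2) single-linkage overlap components over all peaks of all sets:
## returns, per input peak, a component id. Independent of mergeUnion.
overlapComponentsOracle <- function(chrom, start, end) {
  n <- length(start)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (chrom[i] == chrom[j] && start[i] <= end[j] &&
          start[j] <= end[i] && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

## All-pairs site-gene association oracle: site footprint vs gene +/- win.
associationOracle <- function(unions, genes, win = 50000) {
  lapply(seq_along(genes), function(g) {
    gs <- max(start(genes)[g] - win, 1)
    ge <- end(genes)[g] + win
    which(as.character(seqnames(unions)) ==
            as.character(seqnames(genes))[g] &
          start(unions) <= ge & end(unions) >= gs)
  })
}

## Naive sliding-window motif scan (both strands).
naiveScanOracle <- function(seq, motif) {
  rc <- as.character(reverseComplement(DNAString(motif)))
  k <- nchar(motif)
  s <- as.character(seq)
  hits <- integer()
  for (i in seq_len(nchar(s) - k + 1)) {
    sub <- substr(s, i, i + k - 1)
    if (sub == motif || sub == rc) hits <- c(hits, i)
  }
  hits
}

## Exhaustive PWM score-distribution oracle (w <= 8).
pwmTailOracle <- function(pwm, thr, background = rep(0.25, 4)) {
  w <- ncol(pwm)
  lo <- log(pmax(pwm, 1e-12) / background)
  idx <- expand.grid(rep(list(1:4), w))
  sc <- rowSums(sapply(seq_len(w), function(j) lo[cbind(idx[[j]], j)]))
  pr <- apply(sapply(seq_len(w), function(j) background[idx[[j]]]), 1, prod)
  sum(pr[sc >= thr])
}

randomPWM <- function(w, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rgamma(4 * w, 1), 4, w)
  m <- sweep(m, 2, colSums(m), "/")
  rownames(m) <- c("A", "C", "G", "T")
  m
}

## Small, fast simulation configuration for structural tests.
smallSimConfig <- function(seed = 1, ...) {
  args <- list(seed = seed, nChroms = 1L, chromLength = 4000000L,
               nGenes = 40L, nSites = 150L)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(simulationConfig, args)
}
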