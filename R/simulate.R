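## Synthetic three-condition peak-landscape generator with planted binding
## modes, feature-biased placement, planted motifs and coupled expression,
## plus truth manifests for recovery testing.

.defaultModeMeans <- function() {
  m <- rbind(GRADED = c(5, 40, 100),
             LOW_DOMINANT = c(90, 4, 4),
             HIGH_DOMINANT = c(4, 4, 90),
             INVARIANT = c(400, 400, 400))
  colnames(m) <- .CONDITIONS
  m
}

#' Build a simulation configuration
#'
#' Constructs a validated [SimulationConfig-class]. The defaults define the
#' reference synthetic study: two chromosomes of 10 Mb, 300 genes, 1500
#' binding sites, library depths of 10-13 million tags, a mode mixture of
#' 25% graded / 35% low-dominant / 30% high-dominant / 10% invariant with
#' per-mode mean enrichments separated from every classification boundary by
#' at least twice the threshold, feature-biased placement, CAGAC planting at
#' 80% of site centers, and a 2-fold expression coupling with 0.1 log2 noise
#' arranged so that 65% of regulated genes carry differential binding.
#'
#' @param seed Integer master seed; each generator stage derives its own
#'   sub-seed from it, so results are reproducible stage by stage.
#' @param nChroms,chromLength,nGenes,nSites Geometry and scale.
#' @param modeMixture Probability vector over
#'   `GRADED, LOW_DOMINANT, HIGH_DOMINANT, INVARIANT`.
#' @param modeMeans 4 x 3 matrix of expected normalized enrichments.
#' @param depthTriple Library depths per condition.
#' @param featureBias Probability vector over
#'   `promoter, exon, intron, distal, desert` placement categories.
#' @param motifPlantRate Probability that a site carries a planted motif.
#' @param motifSequences Literal motifs to plant (random strand).
#' @param exprCoupling Linear fold change applied to genes near responsive
#'   sites (> 1.5 to clear the regulation cutoff).
#' @param exprNoiseSd Gaussian log2 noise per condition.
#' @param deConcordance Target fraction of regulated genes that carry
#'   differential binding; the remainder are planted as binding-free
#'   regulated genes.
#' @param emitFloor Raw-tag emission floor (strict >), default 12.
#' @param peakWidthRange Site width range in bp.
#' @param testMode Replace Poisson draws by their means (exact assertions).
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(seed = 1L, nChroms = 2L, chromLength = 10000000L,
                             nGenes = 300L, nSites = 1500L,
                             modeMixture = c(GRADED = 0.25,
                                             LOW_DOMINANT = 0.35,
                                             HIGH_DOMINANT = 0.30,
                                             INVARIANT = 0.10),
                             modeMeans = .defaultModeMeans(),
                             depthTriple = c(LOW = 1.2e7, MID = 1.3e7,
                                             HIGH = 1.0e7),
                             featureBias = c(promoter = 0.06, exon = 0.06,
                                             intron = 0.34, distal = 0.34,
                                             desert = 0.2),
                             motifPlantRate = 0.8,
                             motifSequences = "CAGAC",
                             exprCoupling = 2.0, exprNoiseSd = 0.1,
                             deConcordance = 0.65, emitFloor = 12,
                             peakWidthRange = c(200L, 1000L),
                             testMode = FALSE) {
  new("SimulationConfig", seed = as.integer(seed),
      nChroms = as.integer(nChroms), chromLength = as.integer(chromLength),
      nGenes = as.integer(nGenes), nSites = as.integer(nSites),
      modeMixture = modeMixture, modeMeans = modeMeans,
      depthTriple = depthTriple, featureBias = featureBias,
      motifPlantRate = motifPlantRate, motifSequences = motifSequences,
      exprCoupling = exprCoupling, exprNoiseSd = exprNoiseSd,
      deConcordance = deConcordance, emitFloor = emitFloor,
      peakWidthRange = as.integer(peakWidthRange), testMode = testMode)
}

#' Simulate a genome and gene models
#'
#' Generates i.i.d. uniform A/C/G/T chromosomes and places non-overlapping
#' gene models along them, each with 2-10 exons and CDS bounds leaving
#' terminal UTR halves. Genes are laid out with 18-30 kb spacing,
#' interspersed with occasional 160 kb gene-free stretches so that gene
#' deserts (> 50 kb from any gene) exist. Deterministic given the
#' configuration seed.
#'
#' @param config A [simulationConfig()].
#' @return List with `genome` (`DNAStringSet`) and `genes` (`GRanges` as
#'   from [readGeneModels()]).
#' @export
simulateGenome <- function(config) {
  .with_seed(config@seed, {
    genome <- DNAStringSet(vapply(seq_len(config@nChroms), function(i)
      paste(sample(.BASES, config@chromLength, replace = TRUE),
            collapse = ""), character(1)))
    names(genome) <- sprintf("chr%d", seq_len(config@nChroms))
    ng <- config@nGenes
    rows <- vector("list", ng)
    g <- 0L
    if (ng > 0) for (ch in seq_len(config@nChroms)) {
      cursor <- 100000L
      while (g < ng) {
        if (runif(1) < 0.1) cursor <- cursor + 160000L  # desert stretch
        nE <- sample(2:10, 1)
        exw <- sample(150:400, nE, replace = TRUE)
        inw <- if (nE > 1) sample(1500:4000, nE - 1, replace = TRUE)
               else integer()
        glen <- sum(exw) + sum(inw)
        if (cursor + glen > config@chromLength - 100000L) break
        estart <- cursor + cumsum(c(0L, exw[-nE] + inw))
        eend <- estart + exw - 1L
        gi <- g + 1L
        rows[[gi]] <- list(
          chrom = names(genome)[ch], start = cursor,
          end = cursor + glen - 1L,
          strand = sample(c("+", "-"), 1),
          gene_id = sprintf("gene%04d", gi),
          exons = IRanges(estart, eend),
          cs = estart[1] + exw[1] %/% 2L,
          ce = eend[nE] - exw[nE] %/% 2L)
        g <- gi
        cursor <- cursor + glen + sample(18000:30000, 1)
      }
    }
    if (g < ng)
      stop("genome too small to place ", ng, " genes (placed ", g, ")")
    genes <- if (ng == 0)
      .gene_granges(character(), integer(), integer(), character(),
                    character(), IRangesList()) else .gene_granges(
      vapply(rows, `[[`, character(1), "chrom"),
      vapply(rows, `[[`, numeric(1), "start"),
      vapply(rows, `[[`, numeric(1), "end"),
      vapply(rows, `[[`, character(1), "strand"),
      vapply(rows, `[[`, character(1), "gene_id"),
      IRangesList(lapply(rows, `[[`, "exons")),
      vapply(rows, `[[`, numeric(1), "cs"),
      vapply(rows, `[[`, numeric(1), "ce"))
    list(genome = genome, genes = sort(genes, ignore.strand = TRUE))
  })
}

## Exact placement pools: positions whose annotation category is known by
## construction (feature minus all higher-priority features, shrunk by a
## safety margin).
.placementPools <- function(genome, genes, margin = 60L) {
  cfgA <- annotationConfig()
  shrink <- function(gr) {
    gr <- gr[width(gr) > 2 * margin + 10]
    narrow(gr, start = margin + 1L, end = -(margin + 1L))
  }
  if (length(genes)) {
    feats <- .featureRanges(genes, cfgA)
    higher <- GRanges()
    pools <- list()
    for (fc in names(feats)) {
      cur <- reduce(feats[[fc]], ignore.strand = TRUE)
      pools[[fc]] <- setdiff(cur, higher, ignore.strand = TRUE)
      higher <- reduce(c(higher, cur), ignore.strand = TRUE)
    }
  } else {
    pools <- list()
    higher <- GRanges()
  }
  full <- GRanges(names(genome), IRanges(1L, width(genome)))
  desert <- setdiff(full, higher, ignore.strand = TRUE)
  list(promoter = shrink(pools$PROMOTER %||% GRanges()),
       exon = shrink(pools$EXON %||% GRanges()),
       intron = shrink(pools$INTRON %||% GRanges()),
       distal = shrink(reduce(c(pools$DISTAL5 %||% GRanges(),
                                pools$DISTAL3 %||% GRanges()))),
       desert = shrink(desert))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate the three-condition peak landscape
#'
#' For each of `nSites` binding sites, draws a dose-response mode from the
#' mode mixture and a placement category from the feature bias, places the
#' site at a position of that category (sites at least 2 kb apart so
#' cross-condition merging never fuses distinct sites), and emits one peak
#' per condition with raw tag count drawn from
#' `Poisson(mode_mean / depth_scale)` (or its mean in test mode). A
#' condition's peak is emitted only when its raw tag count strictly exceeds
#' the emission floor, mirroring the >12-tag high-confidence cutoff, so
#' background-level conditions produce no peak call.
#'
#' @param config A [simulationConfig()].
#' @param genome,genes Output of [simulateGenome()].
#' @return List with `peaksets` (named list of LOW/MID/HIGH
#'   [PeakSet-class]s) and `truth` (`data.frame`: `site_id`, `chrom`,
#'   `center`, `width`, `mode`, `category`, `motif_planted` — the latter
#'   filled in by [plantMotifs()]).
#' @export
simulatePeakLandscape <- function(config, genome, genes) {
  .with_seed(config@seed + 1L, {
    n <- config@nSites
    pools <- .placementPools(genome, genes)
    # reserve a fraction of genes as binding-free (no site within the 50 kb
    # association window), so expression-only regulated genes exist and the
    # planted DE-binding concordance is attainable
    if (length(genes) > 0) {
      # contiguous blocks: a scattered reservation would blanket the
      # neighbours' pools too, since the exclusion zone spans +/-52 kb
      blocks <- ceiling(seq_along(genes) / 15)
      resBlocks <- sample(unique(blocks),
                          round(0.4 * length(unique(blocks))))
      reserved <- which(blocks %in% resBlocks)
      if (length(reserved)) {
        zone <- reduce(GRanges(
          seqnames(genes)[reserved],
          IRanges(pmax(start(genes)[reserved] - 52000L, 1L),
                  end(genes)[reserved] + 52000L)))
        pools <- lapply(pools, function(p)
          setdiff(p, zone, ignore.strand = TRUE))
      }
    }
    modes <- sample(names(config@modeMixture), n, replace = TRUE,
                    prob = config@modeMixture)
    cats <- sample(names(config@featureBias), n, replace = TRUE,
                   prob = config@featureBias)
    widths <- sample(config@peakWidthRange[1]:config@peakWidthRange[2], n,
                     replace = TRUE)
    accepted <- list()   # per chrom: accepted centers
    chrom <- character(n); center <- integer(n)
    # place scarce categories first so the 2 kb spacing constraint cannot
    # starve them; the drawn per-site categories are unaffected
    ord <- order(match(cats, c("exon", "promoter", "intron", "distal",
                               "desert")))
    for (i in ord) {
      pool <- pools[[cats[i]]]
      if (!length(pool))
        stop("no placement room for category '", cats[i], "'")
      pw <- width(pool)
      ok <- FALSE
      for (try in 1:500) {
        j <- sample.int(length(pool), 1, prob = pw)
        pos <- start(pool)[j] + floor(runif(1) * pw[j])
        ch <- as.character(seqnames(pool))[j]
        near <- accepted[[ch]]
        if (is.null(near) || all(abs(near - pos) >= 2000L)) {
          ok <- TRUE; break
        }
      }
      if (!ok)
        stop("could not place site ", i, " (category '", cats[i],
             "') with 2 kb spacing; enlarge the genome or reduce nSites")
      chrom[i] <- ch; center[i] <- pos
      accepted[[ch]] <- c(accepted[[ch]], pos)
    }
    scale <- 1e7 / config@depthTriple
    peaksets <- lapply(.CONDITIONS, function(cc) {
      mu <- config@modeMeans[modes, cc] / scale[cc]
      raw <- if (config@testMode) round(mu) else rpois(n, mu)
      emit <- raw > config@emitFloor
      s <- center - widths %/% 2L
      gr <- GRanges(chrom[emit],
                    IRanges(s[emit], s[emit] + widths[emit] - 1L),
                    peak_id = sprintf("%s_site%04d", cc, which(emit)),
                    summit = center[emit], raw_tags = raw[emit])
      PeakSet(gr, cc, libraryDepth = config@depthTriple[cc],
              referenceDepth = 1e7)
    })
    names(peaksets) <- .CONDITIONS
    truth <- data.frame(site_id = sprintf("site%04d", seq_len(n)),
                        chrom = chrom, center = center, width = widths,
                        mode = modes, category = cats,
                        motif_planted = FALSE, stringsAsFactors = FALSE)
    list(peaksets = peaksets, truth = truth)
  })
}

#' Plant literal motifs at site centers
#'
#' With probability `motifPlantRate` per site, writes one of the configured
#' motifs (random strand) into the genome starting at the site center, so
#' the planted element sits at the eventual peak summit. Flanking sequence
#' is untouched; the truth manifest's `motif_planted` flag is updated.
#'
#' @param genome `DNAStringSet` from [simulateGenome()].
#' @param truth Truth manifest from [simulatePeakLandscape()].
#' @param config A [simulationConfig()].
#' @return List with the modified `genome` and updated `truth`.
#' @export
plantMotifs <- function(genome, truth, config) {
  .with_seed(config@seed + 2L, {
    if (any(nchar(config@motifSequences) > truth$width))
      stop("motif longer than site")
    plant <- runif(nrow(truth)) < config@motifPlantRate
    for (i in which(plant)) {
      motif <- sample(config@motifSequences, 1)
      if (runif(1) < 0.5) motif <- .revcomp(motif)
      L <- nchar(motif)
      ch <- truth$chrom[i]; s <- truth$center[i]
      if (s + L - 1 > length(genome[[ch]]))
        stop("motif extends beyond chromosome end")
      subseq(genome[[ch]], s, s + L - 1) <- DNAString(motif)
    }
    truth$motif_planted <- plant
    list(genome = genome, truth = truth)
  })
}

## Geometric site-gene association on truth coordinates: gene +/- window vs
## site footprint.
.truthAssociation <- function(genes, truth, window = 50000) {
  gwin <- GRanges(seqnames(genes),
                  IRanges(pmax(start(genes) - window, 1L),
                          end(genes) + window))
  sgr <- GRanges(truth$chrom,
                 IRanges(truth$center - truth$width %/% 2L,
                         truth$center - truth$width %/% 2L +
                           truth$width - 1L))
  findOverlaps(gwin, sgr, ignore.strand = TRUE)
}

#' Simulate a coupled expression table
#'
#' Baseline MID log2 intensities are Normal(7, 1). Genes within 50 kb of a
#' HIGH-responsive site (graded or high-dominant) receive
#' `fc_high_vs_mid = exprCoupling`; genes near a low-dominant site likewise
#' on the LOW contrast; genes near both are co-regulated. Additional
#' binding-free genes are planted as regulated (random contrast and
#' direction) so that the expected fraction of regulated genes carrying
#' differential binding equals `deConcordance`. Gaussian noise of
#' `exprNoiseSd` log2 units is added per condition (skipped in test mode).
#'
#' @param genes Gene models from [simulateGenome()].
#' @param truth Truth manifest from [simulatePeakLandscape()].
#' @param config A [simulationConfig()].
#' @return List with `expression` (`data.frame`: `gene_id`, `LOW`, `MID`,
#'   `HIGH`) and `truthGenes` (`data.frame`: `gene_id`, `true_class`,
#'   `expected_mode`, `has_binding`, `coupled`).
#' @export
simulateExpression <- function(genes, truth, config) {
  .with_seed(config@seed + 3L, {
    ng <- length(genes)
    hits <- .truthAssociation(genes, truth)
    siteModes <- truth$mode
    byGene <- split(subjectHits(hits),
                    factor(queryHits(hits), levels = seq_len(ng)))
    hiResp <- siteModes %in% c("GRADED", "HIGH_DOMINANT")
    loResp <- siteModes == "LOW_DOMINANT"
    hiC <- vapply(byGene, function(s) any(hiResp[s]), logical(1))
    loC <- vapply(byGene, function(s) any(loResp[s]), logical(1))
    hasBinding <- lengths(byGene) > 0
    expectedMode <- vapply(seq_len(ng), function(g) {
      m <- siteModes[byGene[[g]]]
      m <- m[m != "INVARIANT"]
      if (!length(m)) "NONE"
      else if (length(unique(m)) == 1L) m[1] else "MULTIMODAL"
    }, character(1))
    coupled <- hiC | loC
    nFree <- round(sum(coupled) * (1 - config@deConcordance) /
                     config@deConcordance)
    freePool <- which(expectedMode == "NONE")  # no responsive binding
    if (nFree > length(freePool)) {
      warning("only ", length(freePool),
              " genes without responsive binding available for planted DE")
      nFree <- length(freePool)
    }
    free <- if (nFree > 0) sample(freePool, nFree) else integer()
    lfc <- log2(config@exprCoupling)
    mid <- rnorm(ng, 7, 1)
    dHigh <- ifelse(hiC, lfc, 0)
    dLow <- ifelse(loC, lfc, 0)
    for (g in free) {
      contrast <- sample(c("HIGH", "LOW"), 1)
      dir <- sample(c(1, -1), 1)
      if (contrast == "HIGH") dHigh[g] <- dir * lfc else dLow[g] <- dir * lfc
    }
    noise <- function() {
      if (config@testMode || config@exprNoiseSd == 0) numeric(ng)
      else rnorm(ng, 0, config@exprNoiseSd)
    }
    expr <- data.frame(gene_id = genes$gene_id,
                       LOW = mid + dLow + noise(),
                       MID = mid + noise(),
                       HIGH = mid + dHigh + noise(),
                       stringsAsFactors = FALSE)
    cls <- function(dh, dl) {
      h <- dh != 0; l <- dl != 0
      if (h && l) "COREGULATED"
      else if (h) if (dh > 0) "HIGH_SPECIFIC_UP" else "HIGH_SPECIFIC_DOWN"
      else if (l) if (dl > 0) "LOW_SPECIFIC_UP" else "LOW_SPECIFIC_DOWN"
      else "UNCHANGED"
    }
    truthGenes <- data.frame(
      gene_id = genes$gene_id,
      true_class = mapply(cls, dHigh, dLow),
      expected_mode = expectedMode,
      has_binding = hasBinding,
      coupled = coupled, stringsAsFactors = FALSE)
    list(expression = expr, truthGenes = truthGenes)
  })
}
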