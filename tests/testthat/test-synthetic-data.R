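test_that("all four generators are deterministic under a fixed seed", {
  sc <- smallSimConfig(seed = 2)
  a <- simulateGenome(sc)
  b <- simulateGenome(sc)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(granges(a$genes), granges(b$genes))
  la <- simulatePeakLandscape(sc, a$genome, a$genes)
  lb <- simulatePeakLandscape(sc, b$genome, b$genes)
  expect_identical(la$truth, lb$truth)
  expect_identical(peakRanges(la$peaksets$HIGH),
                   peakRanges(lb$peaksets$HIGH))
  pa <- plantMotifs(a$genome, la$truth, sc)
  pb <- plantMotifs(b$genome, lb$truth, sc)
  expect_identical(as.character(pa$genome), as.character(pb$genome))
  ea <- simulateExpression(a$genes, pa$truth, sc)
  eb <- simulateExpression(b$genes, pb$truth, sc)
  expect_identical(ea$expression, eb$expression)
})

test_that("base composition of a simulated chromosome is uniform", {
  sc <- simulationConfig(seed = 3, nChroms = 1L, chromLength = 1000000L,
                         nGenes = 0L, nSites = 10L)
  sim <- simulateGenome(sc)
  expect_length(sim$genes, 0)
  fr <- Biostrings::alphabetFrequency(sim$genome[[1]],
                                      baseOnly = TRUE)[c("A", "C", "G",
                                                         "T")]
  fr <- fr / 1e6
  ci <- 3 * sqrt(0.25 * 0.75 / 1e6)
  expect_true(all(abs(fr - 0.25) <= ci))
})

test_that("an undersized genome refuses to place the genes", {
  sc <- simulationConfig(seed = 4, nChroms = 1L, chromLength = 400000L,
                         nGenes = 50L, nSites = 10L)
  expect_error(simulateGenome(sc), "too small")
})

test_that("gene models are non-overlapping with 2-10 exons and valid CDS", {
  sc <- smallSimConfig(seed = 9)
  sim <- simulateGenome(sc)
  expect_false(any(countOverlaps(sim$genes, sim$genes,
                                 ignore.strand = TRUE) > 1))
  ne <- lengths(sim$genes$exons)
  expect_true(all(ne >= 2 & ne <= 10))
  expect_true(all(sim$genes$cds_start >= start(sim$genes)))
  expect_true(all(sim$genes$cds_end <= end(sim$genes)))
})

test_that("test mode with an invariant mixture classifies invariant downstream", {
  sc <- simulationConfig(seed = 5, nChroms = 1L, chromLength = 4000000L,
                         nGenes = 40L, nSites = 80L,
                         modeMixture = c(GRADED = 0, LOW_DOMINANT = 0,
                                         HIGH_DOMINANT = 0, INVARIANT = 1),
                         testMode = TRUE)
  sim <- simulateGenome(sc)
  land <- simulatePeakLandscape(sc, sim$genome, sim$genes)
  u <- mergeUnion(land$peaksets$LOW, land$peaksets$MID,
                  land$peaksets$HIGH)
  expect_equal(length(u), 80L)
  expect_true(all(classifySites(enrichmentTriple(u)) == "INVARIANT"))
})

test_that("planted graded sites recover their per-condition means", {
  sc <- smallSimConfig(seed = 6, nSites = 300L,
                       modeMixture = c(GRADED = 1, LOW_DOMINANT = 0,
                                       HIGH_DOMINANT = 0, INVARIANT = 0),
                       featureBias = c(promoter = 0, exon = 0,
                                       intron = 0.2, distal = 0.5,
                                       desert = 0.3))
  sim <- simulateGenome(sc)
  land <- simulatePeakLandscape(sc, sim$genome, sim$genes)
  u <- mergeUnion(land$peaksets$LOW, land$peaksets$MID,
                  land$peaksets$HIGH)
  en <- enrichmentTriple(u)
  mm <- sc@modeMeans["GRADED", ]
  for (cc in c("MID", "HIGH")) {
    n <- nrow(en)
    se <- sqrt(mm[cc] / n)   # Poisson-moment standard error (scaled)
    expect_lt(abs(mean(en[, cc]) - mm[cc]), 3 * se * 1.3)
  }
})

test_that("an infinite emission floor silences every peak", {
  sc <- smallSimConfig(seed = 7, emitFloor = Inf)
  sim <- simulateGenome(sc)
  land <- simulatePeakLandscape(sc, sim$genome, sim$genes)
  expect_true(all(vapply(land$peaksets, length, integer(1)) == 0L))
})

test_that("emitted peak counts respond to library depth as expected", {
  # graded LOW mean is near the emission floor, so deeper LOW sequencing
  # must emit more LOW peaks
  mk <- function(dl) {
    sc <- smallSimConfig(seed = 10, nSites = 400L,
                         depthTriple = c(LOW = dl, MID = 1.3e7,
                                         HIGH = 1.0e7),
                         modeMixture = c(GRADED = 1, LOW_DOMINANT = 0,
                                         HIGH_DOMINANT = 0, INVARIANT = 0),
                         featureBias = c(promoter = 0, exon = 0,
                                         intron = 0.2, distal = 0.5,
                                         desert = 0.3))
    sim <- simulateGenome(sc)
    length(simulatePeakLandscape(sc, sim$genome, sim$genes)$peaksets$LOW)
  }
  expect_gt(mk(2.6e7), mk(1.0e7))
})

test_that("every emitted peak joins a truth site by coordinates", {
  sc <- smallSimConfig(seed = 11)
  sim <- simulateGenome(sc)
  land <- simulatePeakLandscape(sc, sim$genome, sim$genes)
  truthPts <- GRanges(land$truth$chrom,
                      IRanges(land$truth$center, land$truth$center))
  for (ps in land$peaksets) {
    gr <- peakRanges(ps)
    hits <- countOverlaps(gr, truthPts)
    expect_true(all(hits == 1))
  }
})

test_that("motif planting follows its rate and leaves flanks untouched", {
  sc <- smallSimConfig(seed = 12, motifPlantRate = 1,
                       motifSequences = "CAGAC")
  sim <- simulateGenome(sc)
  land <- simulatePeakLandscape(sc, sim$genome, sim$genes)
  pm <- plantMotifs(sim$genome, land$truth, sc)
  near <- vapply(seq_len(nrow(pm$truth)), function(i) {
    s <- Biostrings::subseq(pm$genome[[pm$truth$chrom[i]]],
                            pm$truth$center[i] - 2L,
                            pm$truth$center[i] + 6L)
    grepl("CAGAC|GTCTG", as.character(s))
  }, logical(1))
  expect_true(all(near))

  sc0 <- smallSimConfig(seed = 12, motifPlantRate = 0)
  pm0 <- plantMotifs(sim$genome, land$truth, sc0)
  expect_identical(as.character(pm0$genome), as.character(sim$genome))
  expect_false(any(pm0$truth$motif_planted))

  schalf <- smallSimConfig(seed = 13, nSites = 500L, nGenes = 100L,
                           chromLength = 10000000L, motifPlantRate = 0.5,
                           featureBias = c(promoter = 0, exon = 0,
                                           intron = 0.3, distal = 0.55,
                                           desert = 0.15))
  simh <- simulateGenome(schalf)
  landh <- simulatePeakLandscape(schalf, simh$genome, simh$genes)
  pmh <- plantMotifs(simh$genome, landh$truth, schalf)
  k <- sum(pmh$truth$motif_planted)
  ci <- qbinom(c(0.005, 0.995), 500, 0.5)
  expect_gte(k, ci[1]); expect_lte(k, ci[2])

  scbad <- smallSimConfig(seed = 12, motifSequences = paste(
    rep("CAGA", 100), collapse = ""))
  expect_error(plantMotifs(sim$genome, land$truth, scbad), "longer")
})

test_that("expression coupling is exact without noise and unbiased with it", {
  sc <- smallSimConfig(seed = 14, exprNoiseSd = 0)
  sim <- simulateGenome(sc)
  land <- simulatePeakLandscape(sc, sim$genome, sim$genes)
  ex <- simulateExpression(sim$genes, land$truth, sc)
  e <- ex$expression
  fcH <- 2^(e$HIGH - e$MID)
  hi <- ex$truthGenes$true_class %in% c("HIGH_SPECIFIC_UP", "COREGULATED") &
    ex$truthGenes$coupled
  expect_true(all(abs(fcH[hi] - 2.0) < 1e-9))

  # no responsive sites: all fold changes within noise of 1
  scn <- simulationConfig(seed = 15, nChroms = 1L, chromLength = 4000000L,
                          nGenes = 40L, nSites = 60L,
                          modeMixture = c(GRADED = 0, LOW_DOMINANT = 0,
                                          HIGH_DOMINANT = 0,
                                          INVARIANT = 1))
  simn <- simulateGenome(scn)
  landn <- simulatePeakLandscape(scn, simn$genome, simn$genes)
  exn <- simulateExpression(simn$genes, landn$truth, scn)
  fc <- 2^(exn$expression$HIGH - exn$expression$MID)
  unc <- exn$truthGenes$true_class == "UNCHANGED"
  expect_true(all(abs(log2(fc[unc])) < 6 * sqrt(2) * scn@exprNoiseSd))

  # noisy coupling recovers its mean within 3 standard errors
  scb <- smallSimConfig(seed = 16, exprNoiseSd = 0.1)
  simb <- simulateGenome(scb)
  landb <- simulatePeakLandscape(scb, simb$genome, simb$genes)
  exb <- simulateExpression(simb$genes, landb$truth, scb)
  eb <- exb$expression
  cp <- exb$truthGenes$coupled &
    exb$truthGenes$true_class %in% c("HIGH_SPECIFIC_UP", "COREGULATED")
  lfc <- (eb$HIGH - eb$MID)[cp]
  se <- sqrt(2) * 0.1 / sqrt(length(lfc))
  expect_lt(abs(mean(lfc) - 1), 3 * se)
})

test_that("mode means violating their inequalities are rejected", {
  mm <- rbind(GRADED = c(50, 40, 100),
                                   LOW_DOMINANT = c(90, 4, 4),
                                   HIGH_DOMINANT = c(4, 4, 90),
                                   INVARIANT = c(400, 400, 400))
  colnames(mm) <- conditionLevels()
  expect_error(smallSimConfig(seed = 1, modeMeans = mm), "GRADED")
})
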