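test_that("literal motif scanning matches both strands and the naive oracle", {
  expect_equal(scanMotif("ACAGAT", "CAGA"), 2L)          # forward only
  expect_equal(scanMotif("ATCTGA", "CAGA"), 2L)          # via TCTG
  expect_equal(scanMotif("ATCTGA", "CAGA", bothStrands = FALSE), integer())
  expect_error(scanMotif("ACGT", "CAGN"), "ACGT")

  set.seed(23)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  for (motif in c("CAGA", "CAGAC", "ACGTA")) {
    expect_equal(scanMotif(s, motif), naiveScanOracle(s, motif))
  }
})

test_that("positional profiles conserve counts and see planted motifs", {
  sc <- smallSimConfig(seed = 5, motifPlantRate = 1,
                       motifSequences = "CAGAC")
  sim <- simulateGenome(sc)
  land <- simulatePeakLandscape(sc, sim$genome, sim$genes)
  pm <- plantMotifs(sim$genome, land$truth, sc)
  u <- mergeUnion(land$peaksets$LOW, land$peaksets$MID,
                  land$peaksets$HIGH)
  prof <- positionalProfile(u, pm$genome, "CAGAC", flank = 1000, bin = 100)
  expect_equal(sum(prof$bins$count), prof$total)
  central <- prof$bins$frequency[prof$bins$bin_start == 0]
  flanks <- prof$bins$frequency[abs(prof$bins$bin_start + 50) > 300]
  # every region has a planted occurrence at offset zero plus background
  expect_gte(central, 1)
  expect_lt(max(flanks), central / 2)
  expect_error(positionalProfile(u, pm$genome, "CAGAC", flank = 150,
                                 bin = 100), "multiple")
})

test_that("motifs absent from the alphabet give an all-zero profile", {
  genome <- DNAStringSet(c(chr1 = paste(rep("AT", 5000), collapse = "")))
  u <- GRanges("chr1", IRanges(4000, 4200))
  u$presence <- "MID"
  prof <- positionalProfile(u, genome, "CCCC", flank = 500, bin = 100)
  expect_equal(prof$total, 0)
  expect_true(all(prof$bins$count == 0))
})

test_that("clipped regions are dropped from profiles", {
  genome <- DNAStringSet(c(chr1 = paste(rep("ACGT", 1000), collapse = "")))
  u <- GRanges("chr1", IRanges(c(100, 2000), c(140, 2100)))
  u$presence <- c("MID", "MID")
  prof <- positionalProfile(u, genome, "CAGA", flank = 500, bin = 100)
  expect_equal(prof$n_regions, 1)
  expect_equal(prof$dropped, 1)
})

test_that("random background profiles are seed-deterministic and flat", {
  set.seed(77)   # outer RNG state must not leak in
  genome <- DNAStringSet(c(chr1 = paste(sample(c("A", "C", "G", "T"),
                                               3e5, TRUE), collapse = "")))
  b1 <- randomBackgroundProfile(genome, "CAGA", n = 400, flank = 500,
                                bin = 100, seed = 9)
  b2 <- randomBackgroundProfile(genome, "CAGA", n = 400, flank = 500,
                                bin = 100, seed = 9)
  expect_identical(b1, b2)
  b3 <- randomBackgroundProfile(genome, "CAGA", n = 400, flank = 500,
                                bin = 100, seed = 10)
  expect_false(identical(b1$bins$count, b3$bins$count))
  # uniform genome: per-bin frequency close to 2 * bin * (1/4)^k
  p0 <- 2 * 100 * 0.25^4
  se <- sqrt(p0 / (b1$n_regions))   # Poisson-scale error per bin
  expect_true(all(abs(b1$bins$frequency - p0) < 4 * se + 0.05))
  # n = 0 is an empty profile
  b0 <- randomBackgroundProfile(genome, "CAGA", n = 0, flank = 500,
                                bin = 100, seed = 1)
  expect_equal(b0$n_regions, 0)
})

test_that("profiles are invariant under reverse-complementing the genome", {
  set.seed(31)
  L <- 50000L
  genome <- DNAStringSet(c(chr1 = paste(sample(c("A", "C", "G", "T"), L,
                                               TRUE), collapse = "")))
  pos <- sort(sample(seq(2000L, L - 2000L), 20))
  u <- GRanges("chr1", IRanges(pos, pos))
  u$presence <- "MID"
  grc <- DNAStringSet(c(chr1 = as.character(
    reverseComplement(genome[[1]]))))
  # mirrored centers; the full-width window of a width-1 interval shifts by
  # one under mirroring, so mirror around the window itself
  um <- GRanges("chr1", IRanges(L + 1L - pos, L + 1L - pos))
  um$presence <- "MID"
  p1 <- positionalProfile(u, genome, "CAGAC", flank = 500, bin = 100)
  p2 <- positionalProfile(um, grc, "CAGAC", flank = 500, bin = 100)
  expect_equal(p1$total, p2$total)
  expect_equal(sum(p1$bins$count), sum(p2$bins$count))
})

test_that("k-mer center enrichment finds planted motifs and respects bounds", {
  sc <- smallSimConfig(seed = 6, motifPlantRate = 1,
                       motifSequences = "CAGACG")
  sim <- simulateGenome(sc)
  land <- simulatePeakLandscape(sc, sim$genome, sim$genes)
  pm <- plantMotifs(sim$genome, land$truth, sc)
  u <- mergeUnion(land$peaksets$LOW, land$peaksets$MID, land$peaksets$HIGH)
  km <- kmerCenterEnrichment(u, pm$genome, k = 6, centerHalfwidth = 25,
                             flank = 500)
  expect_equal(km$kmer[1], "CAGACG")   # canonical form of the plant
  expect_gte(km$center_fraction[1], 0.99)
  expect_error(kmerCenterEnrichment(u, pm$genome, k = 60,
                                    centerHalfwidth = 25), "narrower")
})

test_that("a k-mer at the very end of the center window still counts", {
  # center window of length 50; place the 6-mer at positions 45-50
  L <- 10000L
  base <- paste(rep("A", L), collapse = "")
  genome <- DNAStringSet(c(chr1 = base))
  center <- 5000L
  # window spans [center-25, center+24]; last 6-mer start = center + 19
  subseq(genome[[1]], center + 19L, center + 24L) <- DNAString("CCGCGG")
  u <- GRanges("chr1", IRanges(center, center))
  u$enrichLOW <- 10; u$enrichMID <- 10; u$enrichHIGH <- 10
  u$presence <- "MID"
  km <- kmerCenterEnrichment(u, genome, k = 6, centerHalfwidth = 25,
                             flank = 200, alpha = 1)
  expect_true("CCGCGG" %in% attr(km, "all")$kmer)
  row <- attr(km, "all")["CCGCGG" == attr(km, "all")$kmer, ]
  expect_equal(row$center_count, 1L)
})

test_that("top-region truncation ranks by maximal enrichment", {
  genome <- DNAStringSet(c(chr1 = paste(rep("ACGT", 5000), collapse = "")))
  u <- GRanges("chr1", IRanges(c(5000, 9000, 13000), width = 1))
  u$enrichLOW <- c(5, 50, 20); u$enrichMID <- c(1, 2, 3)
  u$enrichHIGH <- c(10, 20, 90)
  u$presence <- rep("LOW,MID,HIGH", 3)
  km <- kmerCenterEnrichment(u, genome, k = 4, centerHalfwidth = 25,
                             flank = 100, topNRegions = 2, alpha = 1)
  expect_equal(attr(km, "n_regions"), 2)
})
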