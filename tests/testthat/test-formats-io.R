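test_that("bed6plus peaks parse with coordinate conversion and depth scaling", {
  f <- withr::local_tempfile(lines = "chr1 100 200 p1 0 . 150 40")
  ps <- readPeaks(f, "bed6plus", "MID", libraryDepth = 1e7)
  gr <- peakRanges(ps)
  expect_equal(start(gr), 101L)   # 0-based half-open in, 1-based closed out
  expect_equal(end(gr), 200L)
  expect_equal(gr$summit, 151L)
  expect_equal(gr$raw_tags, 40)
  expect_equal(gr$enrichment, 40)  # identity scaling at equal depths

  ps13 <- readPeaks(f, "bed6plus", "MID", libraryDepth = 1.3e7)
  expect_equal(peakRanges(ps13)$enrichment, 40 * 10 / 13, tolerance = 1e-9)
})

test_that("malformed peak lines fail with the offending line number", {
  f <- withr::local_tempfile(lines = c("chr1 100 200 p1 0 . 150 40",
                                       "chr1 200 100 p2 0 . 150 10"))
  expect_error(readPeaks(f, "bed6plus", "LOW", 1e7), "line 2")
  f2 <- withr::local_tempfile(lines = "chr1 xyz 200")
  expect_error(readPeaks(f2, "bed6plus", "LOW", 1e7), "line 1")
})

test_that("overlapping same-condition peaks are merged at read time", {
  f <- withr::local_tempfile(lines = c("chr1 100 200 a 0 . 120 30",
                                       "chr1 150 300 b 0 . 220 50",
                                       "chr1 400 500 c 0 . 450 20"))
  ps <- readPeaks(f, "bed6plus", "HIGH", 1e7)
  gr <- peakRanges(ps)
  expect_length(gr, 2)
  expect_equal(start(gr), c(101L, 401L))
  expect_equal(end(gr), c(300L, 500L))
  expect_equal(gr$raw_tags, c(80, 20))       # tags summed
  expect_equal(gr$summit, c(221L, 451L))     # summit of the larger peak
  expect_true(isDisjoint(gr))
})

test_that("macs_tab dialect reads 1-based coordinates with relative summits", {
  f <- withr::local_tempfile(lines = c(
    "# comment",
    "chrom\tstart\tend\tlength\tsummit\ttags",
    "chr2\t101\t200\t100\t50\t40"))
  ps <- readPeaks(f, "macs_tab", "LOW", 1e7)
  gr <- peakRanges(ps)
  expect_equal(start(gr), 101L)
  expect_equal(end(gr), 200L)
  expect_equal(gr$summit, 150L)   # start + offset - 1
  expect_equal(gr$raw_tags, 40)
})

test_that("peak reading is independent of input line order", {
  lines <- c("chr1 500 600 a 0 . 550 20", "chr1 100 200 b 0 . 150 30",
             "chr2 50 80 c 0 . 60 15")
  f1 <- withr::local_tempfile(lines = lines)
  f2 <- withr::local_tempfile(lines = rev(lines))
  p1 <- readPeaks(f1, "bed6plus", "MID", 1e7)
  p2 <- readPeaks(f2, "bed6plus", "MID", 1e7)
  expect_identical(granges(peakRanges(p1)), granges(peakRanges(p2)))
  expect_identical(peakRanges(p1)$raw_tags, peakRanges(p2)$raw_tags)
})

test_that("doubling the library depth halves every enrichment exactly", {
  ps1 <- makePeakSet("LOW", c(100, 400), c(200, 500), c(30, 50),
                     depth = 1e7)
  ps2 <- makePeakSet("LOW", c(100, 400), c(200, 500), c(30, 50),
                     depth = 2e7)
  expect_equal(peakRanges(ps1)$enrichment,
               2 * peakRanges(ps2)$enrichment)
})

test_that("GTF gene models convert closed coordinates and validate exons", {
  gtf <- c(
    'chr1\tsrc\ttranscript\t101\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\tCDS\t151\t350\t.\t+\t.\tgene_id "g1"; transcript_id "t1";')
  f <- withr::local_tempfile(lines = gtf, fileext = ".gtf")
  g <- readGeneModels(f, "gtf")
  expect_equal(start(g), 101L)
  expect_equal(end(g), 400L)
  expect_equal(as.integer(unlist(start(g$exons))), c(101L, 301L))
  expect_equal(g$cds_start, 151L)
  expect_equal(g$cds_end, 350L)

  bad <- c(gtf[1], 'chr1\tsrc\texon\t50\t90\t.\t+\t.\tgene_id "g1"; transcript_id "t1";')
  fb <- withr::local_tempfile(lines = bad, fileext = ".gtf")
  expect_error(readGeneModels(fb, "gtf"), "outside transcript bounds")
})

test_that("BED12 blocks become absolute exons and roundtrip footprints", {
  f <- withr::local_tempfile(
    lines = "chr1\t1000\t1200\tg1\t0\t+\t1000\t1200\t0\t2\t50,50\t0,150",
    fileext = ".bed")
  g <- readGeneModels(f, "bed12")
  ex <- g$exons[[1]]
  expect_equal(start(ex), c(1001L, 1151L))  # blockStarts 0,150 from 1000
  expect_equal(end(ex), c(1050L, 1200L))
  # roundtrip through the writer preserves every footprint
  f2 <- withr::local_tempfile(fileext = ".bed")
  writeGeneModels(g, f2)
  g2 <- readGeneModels(f2, "bed12")
  expect_identical(granges(g), granges(g2))
  expect_identical(as.list(g$exons), as.list(g2$exons))
  expect_identical(g$cds_start, g2$cds_start)
})

test_that("TSS is strand-oriented: tx end for minus-strand genes", {
  g <- makeGene("gm", "chr1", 1000, 1999, strand = "-")
  expect_equal(tssPosition(g), 1999)
  expect_equal(ttsPosition(g), 1000)
  gp <- makeGene("gp", "chr1", 1000, 1999, strand = "+")
  expect_equal(tssPosition(gp), 1000)
})

test_that("duplicate gene ids keep the longest transcript", {
  gtf <- c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g"; transcript_id "t1";',
    'chr1\tsrc\texon\t101\t500\t.\t+\t.\tgene_id "g"; transcript_id "t2";')
  f <- withr::local_tempfile(lines = gtf, fileext = ".gtf")
  g <- readGeneModels(f, "gtf")
  expect_length(g, 1)
  expect_equal(end(g), 500L)
})

test_that("expression tables derive fold changes and roundtrip", {
  ex <- data.frame(gene_id = "g1", LOW = 4.0, MID = 5.0, HIGH = 6.0)
  f <- withr::local_tempfile()
  writeExpression(ex, f)
  e <- readExpression(f)
  expect_equal(e$fc_high_vs_mid, 2.0)   # 2^(6-5)
  expect_equal(e$fc_low_vs_mid, 0.5)

  set.seed(1)
  r <- data.frame(gene_id = sprintf("g%02d", 1:10),
                  LOW = round(rnorm(10, 7), 6), MID = round(rnorm(10, 7), 6),
                  HIGH = round(rnorm(10, 7), 6))
  f2 <- withr::local_tempfile()
  writeExpression(r, f2)
  r2 <- readExpression(f2)
  expect_equal(r2[, names(r)], r)

  dup <- rbind(ex, ex)
  f3 <- withr::local_tempfile()
  writeExpression(dup, f3)
  expect_error(readExpression(f3), "duplicate gene_id")
  f4 <- withr::local_tempfile(lines = "gene_id\tLOW\tMID\ng\t1\t2")
  expect_error(readExpression(f4), "HIGH")
})

test_that("FASTA reading uppercases sequence and keys by first token", {
  f <- withr::local_tempfile(lines = c(">s1 some description", "acgtACGT"))
  g <- readGenome(f)
  expect_equal(names(g), "s1")
  expect_equal(as.character(g[[1]]), "ACGTACGT")
})
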