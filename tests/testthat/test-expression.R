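test_that("regulation classes follow the strict fold-change cutoff", {
  ex <- data.frame(fc_high_vs_mid = c(2.0, 1.5, 1.8, 1.0, 0.5, 1.0),
                   fc_low_vs_mid = c(1.0, 1.0, 0.5, 2.2, 1.0, 1 / 1.6))
  expect_equal(classifyRegulation(ex),
               c("HIGH_SPECIFIC_UP", "UNCHANGED", "COREGULATED",
                 "LOW_SPECIFIC_UP", "HIGH_SPECIFIC_DOWN",
                 "LOW_SPECIFIC_DOWN"))
  expect_error(classifyRegulation(
    data.frame(fc_high_vs_mid = -1, fc_low_vs_mid = 1)), "positive")
})

test_that("regulation classification is symmetric in the two contrasts", {
  set.seed(17)
  fh <- 2^rnorm(100, 0, 1); fl <- 2^rnorm(100, 0, 1)
  a <- classifyRegulation(data.frame(fc_high_vs_mid = fh,
                                     fc_low_vs_mid = fl))
  b <- classifyRegulation(data.frame(fc_high_vs_mid = fl,
                                     fc_low_vs_mid = fh))
  swap <- c(HIGH_SPECIFIC_UP = "LOW_SPECIFIC_UP",
            HIGH_SPECIFIC_DOWN = "LOW_SPECIFIC_DOWN",
            LOW_SPECIFIC_UP = "HIGH_SPECIFIC_UP",
            LOW_SPECIFIC_DOWN = "HIGH_SPECIFIC_DOWN",
            COREGULATED = "COREGULATED", UNCHANGED = "UNCHANGED")
  expect_equal(unname(swap[a]), b)
})

.flagFixture <- function(summed, presence2 = NULL) {
  genes <- makeGene("g1", "chr1", 100001, 120000, "+")
  u <- GRanges("chr1", IRanges(c(90000, 95000), c(90500, 95500)))
  en <- if (is.null(presence2)) rbind(summed / 2, summed / 2)
        else rbind(summed, presence2)
  u$enrichLOW <- en[, 1]; u$enrichMID <- en[, 2]; u$enrichHIGH <- en[, 3]
  u$rawMaxLOW <- en[, 1]; u$rawMaxMID <- en[, 2]; u$rawMaxHIGH <- en[, 3]
  u$presence <- apply(en > 0, 1, function(p)
    paste(conditionLevels()[p], collapse = ","))
  gb <- associateGenes(u, genes, doseResponseConfig(minTags = 0))
  list(gb = gb, u = u)
}

test_that("binding-change flags fire on fold change and location change", {
  # (a) summed 100/100/160: ratio 1.6 > 1.5
  fx <- .flagFixture(c(100, 100, 160))
  expect_true(bindingChangeFlags(fx$gb, fx$u, doseResponseConfig(minTags = 0)))
  # identical triples, identical sites: no flag
  fx2 <- .flagFixture(c(100, 100, 100))
  expect_false(bindingChangeFlags(fx2$gb, fx2$u,
                                  doseResponseConfig(minTags = 0)))
  # (c) same summed totals and site counts, but the LOW condition binds a
  # different location
  fx3 <- .flagFixture(c(0, 50, 50), presence2 = c(50, 0, 0))
  expect_true(bindingChangeFlags(fx3$gb, fx3$u,
                                 doseResponseConfig(minTags = 0)))
})

test_that("de-binding fraction covers the degenerate cases and is monotone", {
  gb <- DataFrame(gene_id = c("a", "b", "c"),
                  sites = IntegerList(list(1L, 2L, integer())))
  flags <- c(TRUE, FALSE, FALSE)
  r <- deBindingFraction(c("a", "b", "c"), gb, flags)
  expect_equal(r$fraction, 1 / 3)
  expect_equal(unname(r$counts["with_binding"]), 2L)
  # no regulated gene has a site
  r0 <- deBindingFraction("c", gb, flags)
  expect_equal(r0$fraction, 0)
  # every regulated gene flagged
  r1 <- deBindingFraction(c("a", "b"), gb, c(TRUE, TRUE, FALSE))
  expect_equal(r1$fraction, 1)
  # monotone nondecreasing in the flag set
  expect_true(r1$fraction >=
                deBindingFraction(c("a", "b"), gb, flags)$fraction)
  # empty regulated set: undefined fraction with counts
  rNA <- deBindingFraction(character(), gb, flags)
  expect_true(is.na(rNA$fraction))
  expect_equal(unname(rNA$counts["regulated"]), 0L)
})

test_that("constant binding gives a flat trend at the normalized level", {
  n <- 200
  expr <- data.frame(gene_id = sprintf("g%03d", 1:n),
                     MID = seq(6, 10, length.out = n))
  largest <- data.frame(gene_id = expr$gene_id, LOW = 7, MID = 7, HIGH = 7)
  tr <- bindingExpressionTrend(expr, largest, window = 50)
  expect_equal(unique(round(tr$value, 12)), 1)
  expect_equal(nrow(tr[tr$condition == "MID", ]), n - 50 + 1)
})

test_that("a window equal to the ranked count collapses to the global mean", {
  n <- 60
  set.seed(18)
  expr <- data.frame(gene_id = sprintf("g%03d", 1:n),
                     MID = seq(6, 10, length.out = n))
  largest <- data.frame(gene_id = expr$gene_id,
                        LOW = runif(n, 0, 50), MID = runif(n, 10, 60),
                        HIGH = runif(n, 0, 50))
  tr <- bindingExpressionTrend(expr, largest, window = n)
  hi <- tr[tr$condition == "HIGH", ]
  expect_equal(nrow(hi), 1)
  expect_equal(hi$value, mean(largest$HIGH) / mean(largest$MID))
})

test_that("the expression cutoff excludes genes and enforces the window", {
  expr <- data.frame(gene_id = c("a", "b", "c"), MID = c(5.5, 6, 7))
  largest <- data.frame(gene_id = expr$gene_id, LOW = 1, MID = 1, HIGH = 1)
  expect_error(bindingExpressionTrend(expr, largest, window = 3),
               "window <= 2")   # MID == 5.5 is excluded (strict)
  tr <- bindingExpressionTrend(expr, largest, window = 2)
  expect_equal(nrow(tr[tr$condition == "LOW", ]), 1)
})

test_that("the trend curve is invariant to uniform enrichment rescaling", {
  n <- 120
  set.seed(19)
  expr <- data.frame(gene_id = sprintf("g%03d", 1:n),
                     MID = rnorm(n, 8, 1))
  largest <- data.frame(gene_id = expr$gene_id,
                        LOW = runif(n, 0, 50), MID = runif(n, 10, 60),
                        HIGH = runif(n, 0, 50))
  l2 <- largest
  l2[conditionLevels()] <- largest[conditionLevels()] * 37
  t1 <- bindingExpressionTrend(expr, largest, window = 30)
  t2 <- bindingExpressionTrend(expr, l2, window = 30)
  expect_equal(t1$value, t2$value)
})
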