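## Integration of binding with differential expression: regulated gene
## subsets, binding-change concordance, and the binding-vs-expression
## moving-average trend.

#' Classify genes by expression regulation pattern
#'
#' A contrast counts as changed when its linear fold change strictly exceeds
#' `cutoff` or falls strictly below `1/cutoff` (default 1.5-fold against the
#' MID control). `HIGH_SPECIFIC_*` when only the HIGH-vs-MID contrast
#' changes (direction suffix `UP`/`DOWN`), `LOW_SPECIFIC_*` when only
#' LOW-vs-MID, `COREGULATED` when both change, `UNCHANGED` otherwise.
#'
#' @param expr Expression `data.frame` from [readExpression()] (needs
#'   `fc_high_vs_mid`, `fc_low_vs_mid`).
#' @param cutoff Fold-change cutoff (default 1.5, strict inequality).
#' @return Character vector of regulation classes.
#' @examples
#' classifyRegulation(data.frame(fc_high_vs_mid = c(2, 1.5, 1.8),
#'                               fc_low_vs_mid = c(1, 1, 0.5)))
#' @export
classifyRegulation <- function(expr, cutoff = 1.5) {
  fh <- expr$fc_high_vs_mid; fl <- expr$fc_low_vs_mid
  if (any(!is.finite(fh) | !is.finite(fl) | fh <= 0 | fl <= 0))
    stop("fold changes must be finite and positive")
  hUp <- fh > cutoff; hDn <- fh < 1 / cutoff
  lUp <- fl > cutoff; lDn <- fl < 1 / cutoff
  h <- hUp | hDn; l <- lUp | lDn
  out <- rep("UNCHANGED", length(fh))
  out[h & !l] <- ifelse(hUp[h & !l], "HIGH_SPECIFIC_UP",
                        "HIGH_SPECIFIC_DOWN")
  out[l & !h] <- ifelse(lUp[l & !h], "LOW_SPECIFIC_UP", "LOW_SPECIFIC_DOWN")
  out[h & l] <- "COREGULATED"
  out
}

#' Per-gene binding-change flags
#'
#' A gene is flagged as showing differential binding when any of:
#' (a) the pseudocount-floored summed enrichment ratio between any two
#' conditions exceeds `foldThreshold` (strictly); (b) the number of sites
#' present differs between conditions; (c) the set of site footprints
#' present (above the tag floor) differs between conditions — a change of
#' binding location even at equal totals.
#'
#' @param geneBinding [associateGenes()] result.
#' @param unions The `unions` passed to [associateGenes()] (used for the
#'   per-condition presence of each site).
#' @param cfg A [doseResponseConfig()].
#' @return Logical vector, one flag per gene.
#' @export
bindingChangeFlags <- function(geneBinding, unions,
                               cfg = doseResponseConfig()) {
  idx <- metadata(geneBinding)$siteIndex
  en <- enrichmentTriple(unions[idx])
  eps <- cfg$pseudocount; f <- cfg$foldThreshold
  summed <- cbind(geneBinding$summedLOW, geneBinding$summedMID,
                  geneBinding$summedHIGH)
  sf <- pmax(summed, eps)
  ratio <- apply(sf, 1, max) / apply(sf, 1, min)
  flagA <- ratio > f
  ns <- cbind(geneBinding$nSitesLOW, geneBinding$nSitesMID,
              geneBinding$nSitesHIGH)
  flagB <- apply(ns, 1, function(x) max(x) != min(x))
  flagC <- vapply(seq_len(nrow(geneBinding)), function(g) {
    i <- geneBinding$sites[[g]]
    if (!length(i)) return(FALSE)
    pres <- en[i, , drop = FALSE] > 0
    # footprint sets differ iff some site is present in one condition and
    # absent in another
    any(apply(pres, 1, function(p) any(p) && !all(p)))
  }, logical(1))
  flagA | flagB | flagC
}

#' Fraction of regulated genes with concordant differential binding
#'
#' Among expression-regulated genes, the fraction that both have at least
#' one associated binding site and are flagged as differentially bound
#' ([bindingChangeFlags()]). Counts are reported for both the raw regulated
#' denominator and the subset of regulated genes present in the binding
#' table (genes can drop out of either input upstream).
#'
#' @param regulated Character vector of regulated gene ids.
#' @param geneBinding [associateGenes()] result.
#' @param flags Logical vector from [bindingChangeFlags()], parallel to
#'   `geneBinding`.
#' @return List with `fraction` (NA when no regulated genes), `counts`
#'   (named: regulated, matched, with_binding, concordant) and
#'   `fraction_matched` (denominator restricted to genes present in the
#'   binding table).
#' @export
deBindingFraction <- function(regulated, geneBinding, flags) {
  regulated <- unique(regulated)
  nReg <- length(regulated)
  m <- match(regulated, geneBinding$gene_id)
  matched <- !is.na(m)
  hasSite <- matched & lengths(geneBinding$sites)[ifelse(matched, m, 1)] > 0
  conc <- hasSite & flags[ifelse(matched, m, 1)]
  counts <- c(regulated = nReg, matched = sum(matched),
              with_binding = sum(hasSite), concordant = sum(conc))
  list(fraction = if (nReg > 0) sum(conc) / nReg else NA_real_,
       fraction_matched = if (sum(matched) > 0) sum(conc) / sum(matched)
                          else NA_real_,
       counts = counts)
}

#' Binding-versus-expression moving-average trend
#'
#' Ranks genes by their MID-condition log2 expression (genes at or below
#' `cutoff` are excluded as non-expressed), takes each gene's largest
#' associated peak enrichment per condition (0 when the gene has no site),
#' normalizes all three conditions by the mean MID enrichment over the
#' included genes, and applies an unweighted moving average of `window`
#' genes along the expression ranking.
#'
#' @param expr Expression `data.frame` (`gene_id`, `MID` log2 values).
#' @param largest `data.frame` with columns `gene_id`, `LOW`, `MID`, `HIGH`
#'   of largest-peak enrichments per gene (see [geneLargest()]).
#' @param cutoff MID log2 expression cutoff (default 5.5, strict: genes
#'   with `MID <= cutoff` are dropped).
#' @param window Moving-average window in genes (default 500).
#' @return `data.frame` with columns `rank` (window start rank along
#'   increasing expression), `condition`, `value`; the curve has
#'   `n_ranked - window + 1` points per condition.
#' @export
bindingExpressionTrend <- function(expr, largest, cutoff = 5.5,
                                   window = 500) {
  keep <- expr$MID > cutoff
  n <- sum(keep)
  if (n < window)
    stop("only ", n, " genes pass the expression cutoff; ",
         "use a moving-average window <= ", n)
  e <- expr[keep, ]
  ord <- order(e$MID)
  e <- e[ord, ]
  m <- match(e$gene_id, largest$gene_id)
  val <- sapply(.CONDITIONS, function(cc) {
    v <- largest[[cc]][m]
    v[is.na(v)] <- 0
    v
  })
  norm <- mean(val[, "MID"])
  if (norm == 0) stop("mean MID enrichment is zero; nothing to normalize to")
  val <- val / norm
  ma <- function(x) {
    cs <- c(0, cumsum(x))
    (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  }
  out <- do.call(rbind, lapply(.CONDITIONS, function(cc)
    data.frame(rank = seq_len(n - window + 1), condition = cc,
               value = ma(val[, cc]))))
  rownames(out) <- NULL
  out
}

#' Largest-peak enrichment table of a gene-binding result
#'
#' @param geneBinding [associateGenes()] result.
#' @return `data.frame` with columns `gene_id`, `LOW`, `MID`, `HIGH`
#'   suitable for [bindingExpressionTrend()].
#' @export
geneLargest <- function(geneBinding) {
  data.frame(gene_id = geneBinding$gene_id,
             LOW = geneBinding$largestLOW,
             MID = geneBinding$largestMID,
             HIGH = geneBinding$largestHIGH,
             stringsAsFactors = FALSE)
}
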