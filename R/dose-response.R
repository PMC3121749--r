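## Site-gene association within +/-50 kb and classification of binding
## into dose-response modes.

#' Dose-response classification parameters
#'
#' @param minTags High-confidence raw-tag cutoff: a site is kept only when
#'   its raw tag count strictly exceeds `minTags` in at least one condition
#'   (default 12).
#' @param foldThreshold `f`, the dominance/graded span threshold
#'   (default 1.5).
#' @param responsiveThreshold `r`, the minimal variation for a site to be
#'   considered responsive at all, and the minimal step between adjacent
#'   conditions of a graded site (default 1.25). Must satisfy
#'   `f > r > 1`.
#' @param pseudocount Floor applied to normalized enrichments before ratios
#'   are formed, representing loss of binding indistinguishable from
#'   background (default 1).
#' @param assocWindow Gene association window in bp on either side of the
#'   transcript (default 50000).
#' @return Named list of class `DoseResponseConfig`.
#' @export
doseResponseConfig <- function(minTags = 12, foldThreshold = 1.5,
                               responsiveThreshold = 1.25, pseudocount = 1,
                               assocWindow = 50000) {
  stopifnot(foldThreshold > responsiveThreshold, responsiveThreshold > 1,
            pseudocount > 0, minTags >= 0, assocWindow > 0)
  structure(list(minTags = minTags, foldThreshold = foldThreshold,
                 responsiveThreshold = responsiveThreshold,
                 pseudocount = pseudocount, assocWindow = assocWindow),
            class = "DoseResponseConfig")
}

#' Associate union binding sites with genes
#'
#' A site is associated with every gene whose transcript, extended by
#' `assocWindow` bp on both sides, intersects the site's footprint (so a
#' site may serve multiple genes and a gene may collect multiple sites).
#' Sites whose raw tag count does not exceed `minTags` in any condition are
#' discarded as below the high-confidence floor. For each gene the largest
#' associated site per condition (by normalized enrichment, ties to the
#' leftmost site) and the per-condition sum of enrichments over all
#' associated sites are recorded; the largest peaks of different conditions
#' need not be the same site.
#'
#' @param unions `GRanges` from [mergeUnion()].
#' @param genes Gene models ([readGeneModels()]).
#' @param cfg A [doseResponseConfig()].
#' @return [S4Vectors::DataFrame] with one row per gene: `gene_id`,
#'   `sites` (`IntegerList` of indices into the *filtered* site set, which
#'   is attached as attribute/metadata column set `siteIndex` pointing back
#'   into `unions`), `largestLOW/MID/HIGH`, `summedLOW/MID/HIGH`,
#'   `nSitesLOW/MID/HIGH`. The metadata slot carries `siteIndex`, the
#'   indices of the retained sites in the input `unions`.
#' @export
associateGenes <- function(unions, genes, cfg = doseResponseConfig()) {
  raw <- rawMaxTriple(unions)
  keep <- which(apply(raw, 1, max) > cfg$minTags)
  u <- unions[keep]
  en <- enrichmentTriple(u)
  win <- GRanges(seqnames(genes),
                 IRanges(pmax(start(genes) - cfg$assocWindow, 1L),
                         end(genes) + cfg$assocWindow))
  hits <- findOverlaps(win, u, ignore.strand = TRUE)
  ng <- length(genes)
  sites <- vector("list", ng)
  sp <- split(subjectHits(hits), factor(queryHits(hits), levels = seq_len(ng)))
  sites <- unname(lapply(sp, function(i) sort(unname(i))))
  largest <- matrix(0, ng, 3, dimnames = list(NULL, .CONDITIONS))
  summed <- matrix(0, ng, 3, dimnames = list(NULL, .CONDITIONS))
  nsit <- matrix(0L, ng, 3, dimnames = list(NULL, .CONDITIONS))
  for (g in seq_len(ng)) {
    i <- sites[[g]]
    if (!length(i)) next
    e <- en[i, , drop = FALSE]
    summed[g, ] <- colSums(e)
    nsit[g, ] <- colSums(e > 0)
    # ties to the leftmost site: which.max returns the first maximum and
    # sites are in genomic order
    largest[g, ] <- apply(e, 2, max)
  }
  cv <- function(m, j) unname(m[, j])
  out <- DataFrame(gene_id = genes$gene_id,
                   sites = IntegerList(sites),
                   largestLOW = cv(largest, 1), largestMID = cv(largest, 2),
                   largestHIGH = cv(largest, 3),
                   summedLOW = cv(summed, 1), summedMID = cv(summed, 2),
                   summedHIGH = cv(summed, 3),
                   nSitesLOW = as.integer(cv(nsit, 1)),
                   nSitesMID = as.integer(cv(nsit, 2)),
                   nSitesHIGH = as.integer(cv(nsit, 3)))
  metadata(out) <- list(siteIndex = keep, cfg = cfg)
  out
}

#' Classify enrichment triples into dose-response binding modes
#'
#' Applies the mode rules to per-condition normalized enrichment triples
#' `(e_L, e_M, e_H)`. Enrichments are floored at the pseudocount
#' (`e' = max(e, eps)`: loss of binding is indistinguishable from
#' background), then the first matching rule wins:
#'
#' 1. `INVARIANT` — `max(e')/min(e') < r`: no appreciable variation.
#' 2. `GRADED` — occupancy monotone increasing with signaling
#'    (`e'_H >= e'_M >= e'_L`), full span `e'_H/e'_L >= f`, and both steps
#'    appreciable (`e'_H/e'_M >= r`, `e'_M/e'_L >= r`, the MID condition
#'    showing a moderate intermediate response).
#' 3. `HIGH_DOMINANT` — `e'_H / max(e'_M, e'_L) >= f`: binding essentially
#'    confined to high signaling.
#' 4. `LOW_DOMINANT` — `e'_L / max(e'_M, e'_H) >= f`.
#' 5. `COMPLEX` otherwise (including monotone-decreasing patterns short of
#'    LOW dominance; a graded mode is defined only in the increasing
#'    direction).
#'
#' Classification is total, deterministic, and invariant to uniform
#' positive scaling of triples above the pseudocount floor.
#'
#' @param triples Numeric matrix with columns `LOW`, `MID`, `HIGH` (or a
#'   length-3 vector for a single site).
#' @param cfg A [doseResponseConfig()].
#' @return Character vector of modes (see [bindingModes()]).
#' @examples
#' classifySites(rbind(c(0, 51, 107),   # graded
#'                     c(80, 0, 0),     # low-signaling dominant
#'                     c(0, 0, 90),     # high-signaling dominant
#'                     c(50, 50, 50)))  # invariant
#' @export
classifySites <- function(triples, cfg = doseResponseConfig()) {
  if (is.null(dim(triples))) triples <- matrix(triples, nrow = 1)
  if (ncol(triples) != 3) stop("triples must have 3 columns (LOW, MID, HIGH)")
  if (any(triples < 0)) stop("negative enrichment")
  eL <- pmax(triples[, 1], cfg$pseudocount)
  eM <- pmax(triples[, 2], cfg$pseudocount)
  eH <- pmax(triples[, 3], cfg$pseudocount)
  f <- cfg$foldThreshold; r <- cfg$responsiveThreshold
  hi <- pmax(eL, eM, eH); lo <- pmin(eL, eM, eH)
  mode <- rep("COMPLEX", length(eL))
  inv <- hi / lo < r
  grad <- !inv & eH >= eM & eM >= eL & eH / eL >= f & eH / eM >= r &
    eM / eL >= r
  hidom <- !inv & !grad & eH / pmax(eM, eL) >= f
  lodom <- !inv & !grad & !hidom & eL / pmax(eM, eH) >= f
  mode[inv] <- "INVARIANT"
  mode[grad] <- "GRADED"
  mode[hidom] <- "HIGH_DOMINANT"
  mode[lodom] <- "LOW_DOMINANT"
  mode
}

#' Gene-level dose-response mode
#'
#' A gene's mode summarises the modes of its associated responsive sites
#' (responsive = any site not classified `INVARIANT`): `NONE` when the gene
#' has no responsive site, the shared mode when all responsive sites agree,
#' and `MULTIMODAL` when at least two responsive sites disagree.
#'
#' @param geneBinding [associateGenes()] result.
#' @param siteModes Modes of the *filtered* site set the `geneBinding` rows
#'   index into (i.e. `classifySites(enrichmentTriple(unions)[idx, ])` with
#'   `idx = metadata(geneBinding)$siteIndex`).
#' @return Character vector of gene modes, one per gene.
#' @export
classifyGenes <- function(geneBinding, siteModes) {
  vapply(seq_len(nrow(geneBinding)), function(g) {
    m <- siteModes[geneBinding$sites[[g]]]
    m <- m[m != "INVARIANT"]
    if (!length(m)) "NONE"
    else if (length(unique(m)) == 1L) m[1]
    else "MULTIMODAL"
  }, character(1))
}

#' Mode proportion statistics
#'
#' Counts and percentages of dose-response modes over sites and genes.
#' Site percentages are reported over responsive sites (non-`INVARIANT`)
#' with the denominator stated; gene percentages over genes with at least
#' one associated responsive site (gene mode != `NONE`). Both denominators
#' are reported explicitly; with an empty denominator percentages are `NA`.
#'
#' @param siteModes Character vector of site modes.
#' @param geneModes Character vector of gene modes.
#' @return List of class `ModeStatistics` with `sites` and `genes` data
#'   frames (`mode`, `count`, `percent`) and `denominators`.
#' @export
modeStatistics <- function(siteModes, geneModes) {
  respS <- siteModes[siteModes != "INVARIANT"]
  respG <- geneModes[geneModes != "NONE"]
  sdf <- data.frame(mode = .SITE_MODES,
                    count = as.integer(table(factor(siteModes,
                                                    levels = .SITE_MODES))))
  sdf$percent <- ifelse(sdf$mode == "INVARIANT", NA_real_,
                        if (length(respS)) 100 * sdf$count / length(respS)
                        else NA_real_)
  gmodes <- .GENE_MODES
  gdf <- data.frame(mode = gmodes,
                    count = as.integer(table(factor(geneModes,
                                                    levels = gmodes))))
  gdf$percent <- ifelse(gdf$mode == "NONE", NA_real_,
                        if (length(respG)) 100 * gdf$count / length(respG)
                        else NA_real_)
  structure(list(sites = sdf, genes = gdf,
                 denominators = c(responsive_sites = length(respS),
                                  total_sites = length(siteModes),
                                  responsive_genes = length(respG),
                                  total_genes = length(geneModes))),
            class = "ModeStatistics")
}

#' @export
print.ModeStatistics <- function(x, ...) {
  cat("Site modes (percent of", x$denominators["responsive_sites"],
      "responsive sites):\n")
  print(x$sites, row.names = FALSE)
  cat("Gene modes (percent of", x$denominators["responsive_genes"],
      "responsive genes):\n")
  print(x$genes, row.names = FALSE)
  invisible(x)
}
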