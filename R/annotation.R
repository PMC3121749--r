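## Feature-category annotation of union binding sites and TSS-proximal
## binned frequency profiles.

#' Annotation parameters
#'
#' @param promoterHalfwidth Half-width of the promoter window around the TSS
#'   in bp (default 2000, matching the +/-2 kb TSS profile view).
#' @param ttsHalfwidth Half-width of the TTS-proximal window (default 2000).
#' @param distalLimit Maximum distance from a gene for a site to count as
#'   distal rather than gene desert (default 50000, mirroring the +/-50 kb
#'   gene association window).
#' @return A named list of class `AnnotationConfig`.
#' @export
annotationConfig <- function(promoterHalfwidth = 2000, ttsHalfwidth = 2000,
                             distalLimit = 50000) {
  stopifnot(promoterHalfwidth > 0, ttsHalfwidth > 0, distalLimit > 0,
            promoterHalfwidth <= distalLimit)
  structure(list(promoterHalfwidth = promoterHalfwidth,
                 ttsHalfwidth = ttsHalfwidth, distalLimit = distalLimit),
            class = "AnnotationConfig")
}

#' Midpoints of union intervals
#'
#' The condition-independent representative point of a union binding site
#' (summits may disagree across conditions): `start + width %/% 2`,
#' equivalent to the floor of the interval midpoint.
#'
#' @param unions `GRanges`.
#' @return Integer vector of 1-based positions.
#' @export
siteMidpoint <- function(unions) start(unions) + width(unions) %/% 2L

.clip1 <- function(s, e) IRanges(pmax(s, 1L), pmax(e, 0L))

## Build one GRanges of feature intervals per category, in priority order.
.featureRanges <- function(genes, cfg) {
  chrom <- as.character(seqnames(genes))
  str <- as.character(strand(genes))
  tss <- tssPosition(genes)
  tts <- ttsPosition(genes)
  ph <- cfg$promoterHalfwidth; th <- cfg$ttsHalfwidth; dl <- cfg$distalLimit
  out <- list()
  out$PROMOTER <- GRanges(chrom, .clip1(tss - ph, tss + ph))
  n <- length(genes)
  utr5 <- utr3 <- exon <- intron <- vector("list", n)
  for (i in seq_len(n)) {
    ex <- reduce(sort(genes$exons[[i]]))
    body <- IRanges(start(genes)[i], end(genes)[i])
    intron[[i]] <- setdiff(body, ex)
    cs <- genes$cds_start[i]; ce <- genes$cds_end[i]
    if (is.na(cs)) {
      exon[[i]] <- ex
      utr5[[i]] <- IRanges()
      utr3[[i]] <- IRanges()
    } else {
      exon[[i]] <- intersect(ex, IRanges(cs, ce))
      left <- if (start(genes)[i] <= cs - 1)
        intersect(ex, IRanges(start(genes)[i], cs - 1)) else IRanges()
      right <- if (ce + 1 <= end(genes)[i])
        intersect(ex, IRanges(ce + 1, end(genes)[i])) else IRanges()
      if (str[i] == "-") { tmp <- left; left <- right; right <- tmp }
      utr5[[i]] <- left   # 5' side in gene orientation
      utr3[[i]] <- right
    }
  }
  torange <- function(lst) {
    k <- lengths(lst)
    GRanges(rep(chrom, k), unlist(IRangesList(lst), use.names = FALSE))
  }
  out$UTR5 <- torange(utr5)
  out$UTR3 <- torange(utr3)
  out$EXON <- torange(exon)
  out$INTRON <- torange(intron)
  out$TTS_PROX <- GRanges(chrom, .clip1(tts - th, tts + th))
  up <- ifelse(str == "-", tss + 1L, tss - dl)
  upe <- ifelse(str == "-", tss + dl, tss - 1L)
  out$DISTAL5 <- GRanges(chrom, .clip1(up, upe))
  dn <- ifelse(str == "-", tts - dl, tts + 1L)
  dne <- ifelse(str == "-", tts - 1L, tts + dl)
  out$DISTAL3 <- GRanges(chrom, .clip1(dn, dne))
  out
}

## Nearest-TSS gene and strand-oriented offset for midpoint positions.
## Ties (equidistant TSSs) resolve to the lexicographically smaller gene_id.
.nearestTss <- function(chrom, pos, genes) {
  n <- length(pos)
  gene <- rep(NA_character_, n)
  off <- rep(NA_integer_, n)
  gchrom <- as.character(seqnames(genes))
  for (ch in unique(chrom)) {
    gi <- which(gchrom == ch)
    si <- which(chrom == ch)
    if (!length(gi) || !length(si)) next
    tss <- tssPosition(genes)[gi]
    gid <- genes$gene_id[gi]
    gstr <- as.character(strand(genes))[gi]
    d <- abs(outer(pos[si], tss, "-"))
    ord <- order(gid)
    d <- d[, ord, drop = FALSE]
    best <- apply(d, 1, which.min)   # first minimum = smaller gene_id
    sel <- gi[ord][best]
    gene[si] <- genes$gene_id[sel]
    tssb <- tssPosition(genes)[sel]
    sb <- as.character(strand(genes))[sel]
    off[si] <- ifelse(sb == "-", tssb - pos[si], pos[si] - tssb)
  }
  list(gene = gene, offset = off)
}

#' Annotate union binding sites with genomic feature categories
#'
#' Classifies each site by its midpoint ([siteMidpoint()]) into one of the
#' nine categories of [featureCategories()], resolving multi-feature overlap
#' by the fixed priority `PROMOTER > UTR5 > UTR3 > EXON > INTRON > TTS_PROX
#' > DISTAL5 > DISTAL3 > DESERT`. UTRs are only assigned for genes with CDS
#' bounds; exonic positions of non-coding models are `EXON`. Sites farther
#' than `distalLimit` from every gene (or on a chromosome without genes) are
#' `DESERT`. The nearest-TSS gene and the strand-oriented offset to its TSS
#' (negative = upstream of the gene) are reported alongside.
#'
#' @param unions `GRanges` from [mergeUnion()].
#' @param genes `GRanges` of gene models ([readGeneModels()]).
#' @param cfg An [annotationConfig()].
#' @return `data.frame` with one row per site: `category`, `nearest_gene`,
#'   `tss_offset`.
#' @export
annotateSites <- function(unions, genes, cfg = annotationConfig()) {
  n <- length(unions)
  cat <- rep("DESERT", n)
  mid <- siteMidpoint(unions)
  chrom <- as.character(seqnames(unions))
  if (length(genes)) {
    pts <- GRanges(chrom, IRanges(mid, mid))
    feats <- .featureRanges(genes, cfg)
    unassigned <- rep(TRUE, n)
    for (fc in names(feats)) {
      if (!any(unassigned)) break
      hit <- countOverlaps(pts, feats[[fc]], ignore.strand = TRUE) > 0
      take <- unassigned & hit
      cat[take] <- fc
      unassigned[take] <- FALSE
    }
    nt <- .nearestTss(chrom, mid, genes)
  } else {
    nt <- list(gene = rep(NA_character_, n), offset = rep(NA_integer_, n))
  }
  data.frame(category = cat, nearest_gene = nt$gene,
             tss_offset = nt$offset, stringsAsFactors = FALSE)
}

#' Per-condition feature distribution of binding sites
#'
#' For each condition, the percentage of that condition's sites (union
#' intervals whose presence set contains the condition) falling into each
#' feature category.
#'
#' @param unions `GRanges` from [mergeUnion()].
#' @param genes Gene models.
#' @param cfg An [annotationConfig()].
#' @param annotation Optional precomputed [annotateSites()] result.
#' @return `data.frame` with columns `category`, `condition`, `count`,
#'   `percent`. Percentages within a condition sum to 100 (or are `NA`
#'   when the condition has no sites).
#' @export
featureDistribution <- function(unions, genes, cfg = annotationConfig(),
                                annotation = NULL) {
  if (is.null(annotation)) annotation <- annotateSites(unions, genes, cfg)
  out <- do.call(rbind, lapply(.CONDITIONS, function(cc) {
    sel <- grepl(cc, unions$presence, fixed = TRUE)
    tot <- sum(sel)
    cnt <- table(factor(annotation$category[sel],
                        levels = .FEATURE_CATEGORIES))
    data.frame(category = .FEATURE_CATEGORIES, condition = cc,
               count = as.integer(cnt),
               percent = if (tot > 0) 100 * as.integer(cnt) / tot
                         else rep(NA_real_, length(cnt)))
  }))
  rownames(out) <- NULL
  out
}

#' TSS-proximal binned binding profile
#'
#' Bins each site's strand-oriented offset to its nearest TSS into fixed
#' intervals (default 50 bp over +/-2 kb) and reports, per condition, the
#' percentage of that condition's sites per bin. Sites outside the window
#' (or without any gene on their chromosome) are counted in an
#' out-of-window remainder so that all offsets account for 100% of sites.
#'
#' @param unions `GRanges` from [mergeUnion()].
#' @param genes Gene models.
#' @param window Half-width of the profile window in bp (default 2000).
#' @param bin Bin width in bp (default 50); must divide `window`.
#' @param annotation Optional precomputed [annotateSites()] result.
#' @return `data.frame` with columns `bin_start` (strand-oriented offset of
#'   the bin's left edge; negative = upstream), `condition`, `count`,
#'   `percent`; the out-of-window percentage per condition is attached as
#'   attribute `out_of_window`, the per-condition site totals as `totals`.
#' @export
tssProfile <- function(unions, genes, window = 2000, bin = 50,
                       annotation = NULL) {
  if (window %% bin != 0) stop("window must be a multiple of bin")
  if (is.null(annotation)) annotation <- annotateSites(unions, genes)
  starts <- seq(-window, window - bin, by = bin)
  off <- annotation$tss_offset
  oow <- numeric(0); tots <- integer(0)
  out <- do.call(rbind, lapply(.CONDITIONS, function(cc) {
    sel <- grepl(cc, unions$presence, fixed = TRUE)
    tot <- sum(sel)
    o <- off[sel]
    inw <- !is.na(o) & o >= -window & o <= window - 1
    b <- floor(o[inw] / bin) * bin
    cnt <- table(factor(b, levels = starts))
    oow <<- c(oow, setNames(
      if (tot > 0) 100 * sum(!inw) / tot else NA_real_, cc))
    tots <<- c(tots, setNames(tot, cc))
    data.frame(bin_start = starts, condition = cc, count = as.integer(cnt),
               percent = if (tot > 0) 100 * as.integer(cnt) / tot
                         else rep(NA_real_, length(cnt)))
  }))
  rownames(out) <- NULL
  attr(out, "out_of_window") <- oow
  attr(out, "totals") <- tots
  out
}
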