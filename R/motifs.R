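## Positional motif-frequency profiles around binding-site centers and
## exhaustive k-mer center-enrichment discovery.

.revcomp <- function(x)
  as.character(reverseComplement(DNAStringSet(x)))

.with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(seed)
    return(expr)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Scan a sequence for exact occurrences of a literal motif
#'
#' Returns the 1-based start positions of all (including overlapping) exact
#' matches of `motif` and, when `bothStrands`, of its reverse complement —
#' the convention under which a CAGA element is counted whether it reads
#' CAGA or TCTG on the reference strand.
#'
#' @param sequence A `DNAString`, or a character scalar.
#' @param motif Literal motif over A/C/G/T.
#' @param bothStrands Also match the reverse complement (default `TRUE`).
#' @return Sorted integer vector of match start positions.
#' @examples
#' scanMotif("ACAGAT", "CAGA")    # forward match at 2
#' scanMotif("ATCTGA", "CAGA")    # reverse-complement (TCTG) match at 2
#' @export
scanMotif <- function(sequence, motif, bothStrands = TRUE) {
  if (!grepl("^[ACGT]+$", motif)) stop("motif must be an ACGT string")
  if (is.character(sequence)) sequence <- DNAString(sequence)
  pos <- start(matchPattern(motif, sequence))
  if (bothStrands) {
    rc <- .revcomp(motif)
    if (rc != motif) pos <- c(pos, start(matchPattern(rc, sequence)))
  }
  sort(unique(pos))
}

## Extract fixed-width windows around centers, dropping those clipped at
## chromosome ends. Returns DNAStringSet + the surviving center index.
.centerWindows <- function(genome, chrom, centers, left, right) {
  lens <- setNames(width(genome), names(genome))
  s <- centers - left
  e <- centers + right
  ok <- chrom %in% names(genome) & s >= 1 & e <= lens[chrom]
  ok[is.na(ok)] <- FALSE
  seqs <- DNAStringSet(rep("", sum(ok)))
  ii <- which(ok)
  if (length(ii)) {
    byc <- split(ii, chrom[ii])
    parts <- lapply(names(byc), function(ch) {
      i <- byc[[ch]]
      extractAt(genome[[ch]], IRanges(s[i], e[i]))
    })
    seqs <- do.call(c, parts)
    ord <- order(unlist(byc, use.names = FALSE))
    seqs <- seqs[ord]
  }
  list(seqs = seqs, index = which(ok), dropped = sum(!ok))
}

.profileFromCenters <- function(genome, chrom, centers, motif, flank, bin,
                                mode = c("occurrences", "regions")) {
  mode <- match.arg(mode)
  if (flank %% bin != 0) stop("flank must be a multiple of bin")
  k <- nchar(motif)
  cw <- .centerWindows(genome, chrom, centers, flank, flank + k - 2L)
  n <- length(cw$seqs)
  starts <- seq(-flank, flank - bin, by = bin)
  counts <- setNames(numeric(length(starts)), starts)
  total <- 0
  if (n > 0) {
    pats <- unique(c(motif, .revcomp(motif)))
    hits <- do.call(rbind, lapply(pats, function(pp) {
      m <- Biostrings::vmatchPattern(pp, cw$seqs)
      sidx <- startIndex(m)
      per <- vapply(sidx, function(x) if (is.null(x)) 0L else length(x),
                    integer(1))
      st <- unlist(sidx, use.names = FALSE)
      if (is.null(st)) st <- integer()
      data.frame(region = rep(seq_len(n), per), start = st)
    }))
    hits <- hits[hits$start <= 2 * flank, , drop = FALSE]  # inside window
    hits$bin <- floor((hits$start - flank - 1L) / bin) * bin
    if (mode == "regions")
      hits <- unique(hits[, c("region", "bin")])
    tb <- table(factor(hits$bin, levels = starts))
    counts <- counts + as.numeric(tb)
    total <- total + nrow(hits)
  }
  structure(list(
    bins = data.frame(bin_start = starts, count = as.numeric(counts),
                      frequency = if (n > 0) as.numeric(counts) / n
                                  else rep(NA_real_, length(starts))),
    n_regions = n, dropped = cw$dropped, motif = motif, total = total,
    mode = mode), class = "MotifProfile")
}

#' @export
print.MotifProfile <- function(x, ...) {
  cat("MotifProfile of", x$motif, "over", x$n_regions, "regions (",
      x$total, "occurrences,", x$mode, "mode )\n")
  top <- x$bins[order(-x$bins$count), ][1:min(5, nrow(x$bins)), ]
  print(top, row.names = FALSE)
  invisible(x)
}

#' Positional motif profile around binding-site centers
#'
#' Counts occurrences of a literal motif (both strands) in fixed bins
#' indexed by the offset of the match start from the union-interval
#' midpoint, over all sites whose window fits on its chromosome (clipped
#' regions are dropped). Frequency is occurrences per region per bin;
#' `mode = "regions"` instead counts regions with at least one occurrence
#' per bin.
#'
#' @param unions `GRanges` from [mergeUnion()].
#' @param genome `DNAStringSet`.
#' @param motif Literal ACGT motif (e.g. `"CAGA"` or `"CAGAC"`).
#' @param flank Bp on each side of the center (default 1000).
#' @param bin Bin width in bp (default 100); must divide `flank`.
#' @param mode `"occurrences"` (default) or `"regions"`.
#' @return A `MotifProfile` list: `bins` (`bin_start`, `count`,
#'   `frequency`), `n_regions`, `dropped`, `total`.
#' @seealso [randomBackgroundProfile()] for the matched random-location
#'   control.
#' @export
positionalProfile <- function(unions, genome, motif, flank = 1000,
                              bin = 100, mode = "occurrences") {
  .profileFromCenters(genome, as.character(seqnames(unions)),
                      siteMidpoint(unions), motif, flank, bin, mode)
}

#' Motif profile at random genome locations
#'
#' The background control for [positionalProfile()]: the same binned
#' counting around `n` uniformly random, seed-determined genome positions
#' (chromosomes drawn proportional to length).
#'
#' @param genome `DNAStringSet`.
#' @param motif Literal ACGT motif.
#' @param n Number of random locations (default 10000).
#' @param flank,bin,mode As in [positionalProfile()].
#' @param seed Integer seed making the control reproducible.
#' @return A `MotifProfile`.
#' @export
randomBackgroundProfile <- function(genome, motif, n = 10000, flank = 1000,
                                    bin = 100, seed = 1,
                                    mode = "occurrences") {
  if (n == 0)
    return(.profileFromCenters(genome, character(), integer(), motif,
                               flank, bin, mode))
  lens <- width(genome)
  if (max(lens) <= 2 * flank) stop("genome shorter than 2*flank")
  .with_seed(seed, {
    ch <- sample(seq_along(genome), n, replace = TRUE,
                 prob = lens / sum(lens))
    pos <- floor(runif(n, min = 1, max = lens[ch] + 1))
  })
  .profileFromCenters(genome, names(genome)[ch], pos, motif, flank, bin,
                      mode)
}

#' Exhaustive k-mer center enrichment
#'
#' Enumerates every k-mer occurring in the center windows of the binding
#' sites (both strands, canonicalized to the lexicographically smaller of
#' k-mer and reverse complement) and tests whether its center occurrence
#' count exceeds the expectation from its per-position occurrence rate in
#' the flanking sequence (one-sided binomial tail). K-mers whose
#' Benjamini-Hochberg adjusted p-value exceeds `alpha` are excluded;
#' survivors are ranked by p-value, then by center fraction.
#'
#' @param unions `GRanges` from [mergeUnion()].
#' @param genome `DNAStringSet`.
#' @param k K-mer length (6 or 8 in the standard analyses).
#' @param centerHalfwidth Half-width of the center window in bp; the window
#'   has length `2*centerHalfwidth` and a k-mer must lie fully inside it
#'   (default 25).
#' @param flank Bp of flanking sequence on each side of the center window
#'   used to estimate the background rate (default 1000).
#' @param topNRegions If set, only the top-N regions ranked by maximum
#'   enrichment across conditions are used (e.g. the top 1000 peaks).
#' @param alpha BH-adjusted significance cutoff (default 0.01).
#' @return `data.frame` of surviving k-mers: `kmer`, `center_count`,
#'   `center_fraction` (fraction of regions whose center window contains
#'   the k-mer on either strand), `flank_rate` (per-position), `p_value`,
#'   `p_adjusted`, `rank`. The unfiltered table is attached as attribute
#'   `all`; the number of regions used as attribute `n_regions`.
#' @export
kmerCenterEnrichment <- function(unions, genome, k = 6,
                                 centerHalfwidth = 25, flank = 1000,
                                 topNRegions = NULL, alpha = 0.01) {
  if (k > 2 * centerHalfwidth) stop("center window narrower than k")
  u <- unions
  if (!is.null(topNRegions)) {
    sc <- apply(enrichmentTriple(u), 1, max)
    u <- u[order(-sc)][seq_len(min(topNRegions, length(u)))]
  }
  centers <- siteMidpoint(u)
  chrom <- as.character(seqnames(u))
  chw <- centerHalfwidth
  # full region: flank | center (2*chw) | flank
  cw <- .centerWindows(genome, chrom, centers, chw + flank,
                       chw + flank - 1L)
  n <- length(cw$seqs)
  empty <- data.frame(kmer = character(), center_count = integer(),
                      center_fraction = numeric(), flank_rate = numeric(),
                      p_value = numeric(), p_adjusted = numeric(),
                      rank = integer())
  if (n == 0) return(empty)
  centerSeq <- subseq(cw$seqs, flank + 1L, flank + 2L * chw)
  flankL <- subseq(cw$seqs, 1L, flank)
  flankR <- subseq(cw$seqs, flank + 2L * chw + 1L, 2L * flank + 2L * chw)
  # enumerate center k-mers
  cs <- as.character(centerSeq)
  npos <- 2L * chw - k + 1L
  mat <- vapply(seq_len(npos), function(i) substr(cs, i, i + k - 1L),
                character(n))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = n)
  canon <- function(x) pmin(x, .revcomp(x))
  cmat <- matrix(canon(as.vector(mat)), nrow = n)
  kmers <- sort(unique(as.vector(cmat)))
  kmers <- kmers[grepl("^[ACGT]+$", kmers)]
  if (!length(kmers)) return(empty)
  centerCount <- vapply(kmers, function(km) sum(cmat == km), numeric(1))
  centerFrac <- vapply(kmers, function(km)
    sum(rowSums(cmat == km) > 0), numeric(1)) / n
  # flank occurrences of kmer + revcomp via a constant-width dictionary
  rcs <- .revcomp(kmers)
  dict <- unique(c(kmers, rcs))
  pd <- PDict(dict)
  occ <- rowSums(vcountPDict(pd, flankL)) + rowSums(vcountPDict(pd, flankR))
  names(occ) <- dict
  flankOcc <- occ[kmers] + ifelse(rcs == kmers, 0, occ[rcs])
  flankPos <- 2 * n * (flank - k + 1)
  flankRate <- flankOcc / flankPos
  centerPos <- n * npos
  pval <- pbinom(centerCount - 1, centerPos, pmin(flankRate, 1),
                 lower.tail = FALSE)
  padj <- p.adjust(pval, "BH")
  all <- data.frame(kmer = kmers, center_count = as.integer(centerCount),
                    center_fraction = centerFrac, flank_rate = flankRate,
                    p_value = pval, p_adjusted = padj)
  all <- all[order(all$p_value, -all$center_fraction, all$kmer), ]
  rownames(all) <- NULL
  res <- all[all$p_adjusted <= alpha, , drop = FALSE]
  if (nrow(res)) res$rank <- seq_len(nrow(res))
  else res$rank <- integer(0)
  rownames(res) <- NULL
  attr(res, "all") <- all
  attr(res, "n_regions") <- n
  res
}
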