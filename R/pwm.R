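## Position weight matrices: plain-text I/O, exact score-distribution
## thresholds by positionwise convolution, and co-motif enrichment around
## binding sites.

.BASES <- c("A", "C", "G", "T")

#' Read / write a plain-text PWM library
#'
#' One matrix per record: a header line `>id width` followed by four
#' whitespace-separated rows of per-position probabilities in the fixed row
#' order A, C, G, T. Columns must each sum to 1.
#'
#' @param path File path.
#' @return Named list of 4 x width probability matrices with rownames
#'   A/C/G/T.
#' @export
readPWMs <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != ""]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no PWM records in ", path)
  out <- list()
  for (h in seq_along(heads)) {
    i <- heads[h]
    hd <- strsplit(sub("^>", "", lines[i]), "\\s+")[[1]]
    id <- hd[1]
    w <- as.integer(hd[2])
    rows <- lines[(i + 1):(i + 4)]
    m <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(r, "\\s+")[[1]])))
    if (ncol(m) != w) stop("PWM ", id, ": expected width ", w,
                           ", found ", ncol(m))
    rownames(m) <- .BASES
    if (any(abs(colSums(m) - 1) > 1e-4))
      stop("PWM ", id, ": columns must sum to 1")
    out[[id]] <- m
  }
  out
}

#' @rdname readPWMs
#' @param pwms Named list of probability matrices.
#' @export
writePWMs <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(pwms)) {
    m <- pwms[[id]]
    writeLines(sprintf(">%s %d", id, ncol(m)), con)
    for (b in .BASES)
      writeLines(paste(format(m[b, ], digits = 6), collapse = " "), con)
  }
  invisible(path)
}

#' 0-order base composition of a genome
#'
#' Convenience estimator for the `background` argument of
#' [pwmThreshold()] and [comotifEnrichment()].
#'
#' @param genome A `DNAStringSet`.
#' @return Numeric vector of A/C/G/T frequencies summing to 1.
#' @export
baseComposition <- function(genome) {
  f <- colSums(Biostrings::alphabetFrequency(genome)[, .BASES,
                                                     drop = FALSE])
  f / sum(f)
}

## log-odds scoring matrix; zero probabilities score as a large negative
## value (a base the motif forbids)
.pwmLogOdds <- function(pwm, background = rep(0.25, 4)) {
  stopifnot(nrow(pwm) == 4)
  log(pmax(pwm, 1e-12) / background)
}

.revcompPWM <- function(m) {
  out <- m[c("T", "G", "C", "A"), rev(seq_len(ncol(m))), drop = FALSE]
  rownames(out) <- .BASES
  out
}

#' Exact PWM score threshold for a tail probability
#'
#' Computes the distribution of log-odds scores
#' `sum_j log(p[b_j, j] / bg[b_j])` over all `4^w` sequences weighted by the
#' background composition, by positionwise convolution over a discretized
#' score grid (step at most 1e-3 of the total score range divided by the
#' width, so accumulated rounding stays within grid tolerance), and returns
#' the smallest achievable score `t` with `P(score >= t) <= p`. The
#' reported threshold is lowered by the worst-case accumulated rounding
#' (half a grid step per position), so scanning at it never misses a
#' sequence the exact computation selected. When even the maximal score has
#' tail probability above `p`, `Inf` is returned: no sequence can satisfy
#' the threshold.
#'
#' @param pwm 4 x w probability matrix (rows A/C/G/T).
#' @param p Tail probability (in (0, 1]; e.g. 1e-5).
#' @param background Background base composition (default uniform).
#' @return List with `threshold` (log-odds score), `p_attained` (the exact
#'   tail probability at the threshold) and `step` (grid resolution).
#' @examples
#' m <- matrix(c(1, 0, 0, 0), 4, 1, dimnames = list(c("A","C","G","T")))
#' pwmThreshold(m, p = 0.3)$threshold  # selects only A; P = 0.25
#' @export
pwmThreshold <- function(pwm, p = 1e-5, background = rep(0.25, 4)) {
  if (p <= 0 || p > 1) stop("p must be in (0, 1]")
  lo <- .pwmLogOdds(pwm, background)
  w <- ncol(lo)
  rng <- sum(apply(lo, 2, max) - apply(lo, 2, min))
  step <- if (rng > 0) rng * 1e-3 / w else 1e-6
  iscore <- round(lo / step)
  # distribution over integer grid scores, offset-tracked
  dist <- c(1)                      # P(score index = off) with off = 0
  off <- 0
  for (j in seq_len(w)) {
    sj <- iscore[, j]
    lo_j <- min(sj); hi_j <- max(sj)
    newlen <- length(dist) + (hi_j - lo_j)
    nd <- numeric(newlen)
    for (b in 1:4) {
      sh <- sj[b] - lo_j
      nd[(1 + sh):(length(dist) + sh)] <-
        nd[(1 + sh):(length(dist) + sh)] + dist * background[b]
    }
    dist <- nd
    off <- off + lo_j
  }
  scores <- (off + seq_along(dist) - 1) * step
  tail <- rev(cumsum(rev(dist)))
  achievable <- dist > 0
  ok <- which(achievable & tail <= p)
  if (!length(ok))
    return(list(threshold = Inf, p_attained = 0, step = step))
  i <- ok[1]
  # release the grid score by the worst-case accumulated rounding so the
  # reported threshold never excludes a sequence the exact computation
  # selected (the set can widen by at most the boundary mass within one
  # grid tolerance)
  list(threshold = scores[i] - w * step / 2, p_attained = tail[i],
       step = step)
}

#' Co-motif enrichment around binding sites
#'
#' For each PWM in a library, the fraction of peak windows (site center
#' +/- `window` bp) containing at least one match at the PWM's exact
#' score-distribution threshold ([pwmThreshold()], both strands) is
#' compared with the same fraction over `nBackground` random genome windows
#' by a one-sided Fisher exact test. P-values are Benjamini-Hochberg
#' adjusted across the library and PWMs are ranked by their peak-window
#' fraction. Windows clipped at chromosome ends are dropped and their count
#' reported.
#'
#' @param unions `GRanges` from [mergeUnion()].
#' @param genome `DNAStringSet`.
#' @param pwmLibrary Named list of probability matrices ([readPWMs()]).
#' @param window Half-width of the scan window in bp (<= 5000;
#'   default 1000).
#' @param p PWM match tail probability (default 1e-5).
#' @param nBackground Number of random control windows (default 10000).
#' @param seed Seed for the control windows.
#' @param background Base composition for the PWM score model.
#' @return `data.frame` ranked by peak fraction: `id`, `threshold`,
#'   `peak_fraction`, `bg_fraction`, `p_value`, `p_adjusted`, `rank`, with
#'   attributes `n_peak_windows`, `n_background` and `dropped`.
#' @export
comotifEnrichment <- function(unions, genome, pwmLibrary, window = 1000,
                              p = 1e-5, nBackground = 10000, seed = 1,
                              background = rep(0.25, 4)) {
  if (!length(pwmLibrary)) stop("empty PWM library")
  if (window > 5000) stop("window must be <= 5000 bp")
  cw <- .centerWindows(genome, as.character(seqnames(unions)),
                       siteMidpoint(unions), window, window)
  peakSeqs <- cw$seqs
  lens <- width(genome)
  .with_seed(seed, {
    ch <- sample(seq_along(genome), nBackground, replace = TRUE,
                 prob = lens / sum(lens))
    pos <- floor(runif(nBackground, min = 1, max = lens[ch] + 1))
  })
  bw <- .centerWindows(genome, names(genome)[ch], pos, window, window)
  bgSeqs <- bw$seqs
  scanFrac <- function(seqs, lo, thr) {
    if (!is.finite(thr) || !length(seqs)) return(0)
    rc <- .revcompPWM(lo)
    hit <- vapply(seq_along(seqs), function(i) {
      s <- seqs[[i]]
      countPWM(lo, s, min.score = thr) > 0 ||
        countPWM(rc, s, min.score = thr) > 0
    }, logical(1))
    mean(hit)
  }
  ids <- names(pwmLibrary)
  rows <- lapply(ids, function(id) {
    m <- pwmLibrary[[id]]
    th <- pwmThreshold(m, p, background)
    lo <- .pwmLogOdds(m, background)
    pf <- scanFrac(peakSeqs, lo, th$threshold)
    bf <- scanFrac(bgSeqs, lo, th$threshold)
    np <- length(peakSeqs); nb <- length(bgSeqs)
    pv <- if (np == 0 || nb == 0) 1 else
      fisher.test(matrix(c(round(pf * np), np - round(pf * np),
                           round(bf * nb), nb - round(bf * nb)), 2,
                         byrow = TRUE),
                  alternative = "greater")$p.value
    data.frame(id = id, threshold = th$threshold, peak_fraction = pf,
               bg_fraction = bf, p_value = pv)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_value, "BH")
  out <- out[order(-out$peak_fraction, out$p_value, out$id), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "n_peak_windows") <- length(peakSeqs)
  attr(out, "n_background") <- length(bgSeqs)
  attr(out, "dropped") <- cw$dropped + bw$dropped
  out
}
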