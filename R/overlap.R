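## Cross-condition merging of peak calls into union binding sites and the
## three-set Venn partition over their presence sets.

#' Merge three conditions' peaks into union binding sites
#'
#' Performs a single-linkage merge of all peaks across the three conditions:
#' any two peaks sharing at least 1 bp of genomic overlap (chained
#' transitively) end up in the same union interval, whose bounds are the
#' minimum start and maximum end of its members. Abutting intervals (zero
#' overlap) are kept separate. For each condition, the union interval carries
#' the maximum normalized enrichment and maximum raw tag count among that
#' condition's contributing peaks (0 if the condition contributed none).
#'
#' @param low,mid,high [PeakSet-class] objects for the LOW, MID and HIGH
#'   conditions (order-checked: each must carry its own condition label,
#'   and the three labels must be distinct).
#' @return `GRanges` of disjoint, sorted union intervals with metadata
#'   columns `enrichLOW`, `enrichMID`, `enrichHIGH` (max normalized
#'   enrichment per condition), `rawMaxLOW`, `rawMaxMID`, `rawMaxHIGH`,
#'   `members` (`CharacterList` of contributing peak ids) and `presence`
#'   (comma-joined subset of conditions with enrichment > 0).
#' @examples
#' mk <- function(cond, s, e, tags)
#'   PeakSet(GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e),
#'                                  raw_tags = tags), cond, 1e7)
#' u <- mergeUnion(mk("LOW", 101, 200, 10), mk("MID", 151, 250, 20),
#'                 mk("HIGH", 400, 500, 30))
#' u$presence
#' @export
mergeUnion <- function(low, mid, high) {
  sets <- list(low, mid, high)
  labs <- vapply(sets, condition, character(1))
  if (anyDuplicated(labs)) stop("duplicate condition among input PeakSets")
  if (!setequal(labs, .CONDITIONS))
    stop("need one PeakSet per condition LOW, MID, HIGH")
  sets <- sets[match(.CONDITIONS, labs)]
  grl <- lapply(sets, peakRanges)
  all_gr <- do.call(c, lapply(seq_along(grl), function(i) {
    g <- grl[[i]]
    mcols(g) <- DataFrame(peak_id = g$peak_id, raw_tags = g$raw_tags,
                          enrichment = g$enrichment,
                          cond = .CONDITIONS[i])
    g
  }))
  # min.gapwidth = 0: abutting peaks share no base and stay separate
  red <- reduce(all_gr, with.revmap = TRUE, ignore.strand = TRUE,
                min.gapwidth = 0L)
  red <- sort(GenomeInfoDb::sortSeqlevels(red), ignore.strand = TRUE)
  n <- length(red)
  en <- matrix(0, n, 3, dimnames = list(NULL, .CONDITIONS))
  rw <- matrix(0, n, 3, dimnames = list(NULL, .CONDITIONS))
  members <- vector("list", n)
  rv <- red$revmap
  for (i in seq_len(n)) {
    idx <- rv[[i]]
    cond <- all_gr$cond[idx]
    members[[i]] <- all_gr$peak_id[idx]
    for (cc in unique(cond)) {
      sel <- idx[cond == cc]
      en[i, cc] <- max(all_gr$enrichment[sel])
      rw[i, cc] <- max(all_gr$raw_tags[sel])
    }
  }
  red$revmap <- NULL
  red$enrichLOW <- en[, "LOW"]; red$enrichMID <- en[, "MID"]
  red$enrichHIGH <- en[, "HIGH"]
  red$rawMaxLOW <- rw[, "LOW"]; red$rawMaxMID <- rw[, "MID"]
  red$rawMaxHIGH <- rw[, "HIGH"]
  red$members <- CharacterList(members)
  red$presence <- apply(en > 0, 1, function(p)
    paste(.CONDITIONS[p], collapse = ","))
  red
}

#' Extract the per-condition enrichment triple matrix
#'
#' @param unions `GRanges` from [mergeUnion()].
#' @return Numeric matrix with columns `LOW`, `MID`, `HIGH`.
#' @export
enrichmentTriple <- function(unions) {
  cbind(LOW = unions$enrichLOW, MID = unions$enrichMID,
        HIGH = unions$enrichHIGH)
}

#' @rdname enrichmentTriple
#' @export
rawMaxTriple <- function(unions) {
  cbind(LOW = unions$rawMaxLOW, MID = unions$rawMaxMID,
        HIGH = unions$rawMaxHIGH)
}

.SUBSET_ORDER <- c("LOW", "MID", "HIGH", "LOW,MID", "LOW,HIGH", "MID,HIGH",
                   "LOW,MID,HIGH")

#' Three-set Venn partition of union binding sites
#'
#' Counts each union interval once in the Venn segment given by its presence
#' set (the subset of conditions contributing a peak), and reports segment
#' counts and percentages of the union total. Per-condition totals are
#' reported both over union intervals (sum of segments containing the
#' condition) and, when the original `PeakSet`s are supplied, over the
#' pre-merge input peaks (merging can reduce counts, so the two can differ).
#'
#' @param unions `GRanges` from [mergeUnion()].
#' @param peaksets Optional list of the three input [PeakSet-class] objects,
#'   used only to report pre-merge per-condition peak totals.
#' @return A list of class `VennPartition` with elements `counts` (named by
#'   the 7 non-empty subsets), `percentages`, `unionTotal`,
#'   `conditionTotals` and optionally `inputTotals`.
#' @export
vennPartition <- function(unions, peaksets = NULL) {
  pres <- unions$presence
  if (any(pres == "")) stop("union interval with empty presence set")
  counts <- setNames(integer(length(.SUBSET_ORDER)), .SUBSET_ORDER)
  tab <- table(pres)
  counts[names(tab)] <- as.integer(tab)
  total <- length(unions)
  pct <- if (total > 0) 100 * counts / total else counts * NA_real_
  condTot <- vapply(.CONDITIONS, function(cc)
    sum(counts[grepl(cc, .SUBSET_ORDER)]), numeric(1))
  out <- list(counts = counts, percentages = pct, unionTotal = total,
              conditionTotals = condTot)
  if (!is.null(peaksets))
    out$inputTotals <- setNames(
      vapply(peaksets, length, integer(1)),
      vapply(peaksets, condition, character(1)))
  class(out) <- "VennPartition"
  out
}

#' @export
print.VennPartition <- function(x, ...) {
  cat("Venn partition of", x$unionTotal, "union binding sites\n")
  df <- data.frame(segment = names(x$counts), count = as.integer(x$counts),
                   percent = round(x$percentages, 2))
  print(df, row.names = FALSE)
  cat("per-condition union totals:",
      paste(sprintf("%s=%d", names(x$conditionTotals),
                    as.integer(x$conditionTotals)), collapse = " "), "\n")
  if (!is.null(x$inputTotals))
    cat("pre-merge input peak totals:",
        paste(sprintf("%s=%d", names(x$inputTotals),
                      as.integer(x$inputTotals)), collapse = " "), "\n")
  invisible(x)
}

#' @rdname vennPartition
#' @param x A `VennPartition`.
#' @return `vennTable()` returns the partition as a `data.frame` suitable
#'   for [writeTable()].
#' @export
vennTable <- function(x) {
  data.frame(segment = names(x$counts), count = as.integer(x$counts),
             percent = as.numeric(x$percentages))
}

#' Write union intervals as BED6+ with per-condition enrichment columns
#'
#' Columns: `chrom start end name score strand enrichLOW enrichMID
#' enrichHIGH presence` (0-based half-open coordinates).
#'
#' @param unions `GRanges` from [mergeUnion()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeUnions <- function(unions, path) {
  df <- data.frame(chrom = as.character(seqnames(unions)),
                   start = start(unions) - 1L, end = end(unions),
                   name = sprintf("union_%d", seq_along(unions)),
                   score = 0L, strand = ".",
                   enrichLOW = unions$enrichLOW,
                   enrichMID = unions$enrichMID,
                   enrichHIGH = unions$enrichHIGH,
                   presence = unions$presence)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
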