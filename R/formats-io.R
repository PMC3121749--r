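## Readers/writers for the external formats the pipeline consumes and emits.
## Internal containers are Bioconductor-native (GRanges 1-based closed,
## DNAStringSet); 0-based half-open coordinates exist only in BED files and
## are converted at these I/O boundaries.

.split_fields <- function(lines) strsplit(trimws(lines), "[ \t]+")

.num_or_stop <- function(x, what, lineno, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad))
    stop(sprintf("%s: line %d: cannot parse %s ('%s')",
                 basename(path), lineno[bad[1]], what, x[bad[1]]))
  v
}

#' Read peak calls for one condition
#'
#' Parses a peak file into a [PeakSet-class]. Two dialects are supported:
#'
#' * `bed6plus`: whitespace-separated BED6 plus two extra columns —
#'   `chrom start end name score strand summit tags`, with `start` and
#'   `summit` 0-based (half-open intervals) and `summit` an absolute
#'   coordinate or `.` for missing.
#' * `macs_tab`: a MACS-style tab table with header
#'   `chrom start end length summit tags`, 1-based closed intervals and the
#'   summit given as an offset relative to `start`. Lines starting with `#`
#'   are skipped.
#'
#' Coordinates are converted to the internal 1-based closed convention,
#' peaks are sorted, overlapping same-condition peaks merged (tags summed,
#' summit of the larger peak kept), missing summits set to the interval
#' midpoint, and enrichment computed as
#' `raw_tags * referenceDepth / libraryDepth`.
#'
#' @param path Path to the peak file.
#' @param dialect `"bed6plus"` or `"macs_tab"`.
#' @param condition Condition label (`"LOW"`, `"MID"`, `"HIGH"`).
#' @param libraryDepth Total sequenced tags of this library.
#' @param referenceDepth Normalization depth (default 1e7).
#' @return A [PeakSet-class].
#' @seealso [writePeaks()]
#' @export
readPeaks <- function(path, dialect = c("bed6plus", "macs_tab"), condition,
                      libraryDepth, referenceDepth = 1e7) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (dialect == "macs_tab" && length(lines) &&
      grepl("^chrom\t", lines[1])) {
    lines <- lines[-1]
    lineno <- lineno[-1]
  }
  if (!length(lines))
    return(PeakSet(GRanges(raw_tags = integer()), condition,
                   libraryDepth, referenceDepth))
  f <- .split_fields(lines)
  nf <- lengths(f)
  minc <- if (dialect == "bed6plus") 3L else 6L
  if (any(nf < minc))
    stop(sprintf("%s: line %d: expected >= %d columns, found %d",
                 basename(path), lineno[which(nf < minc)[1]], minc,
                 min(nf)))
  getcol <- function(i) vapply(f, function(x)
    if (length(x) >= i) x[i] else NA_character_, character(1))
  chrom <- getcol(1)
  if (dialect == "bed6plus") {
    start0 <- .num_or_stop(getcol(2), "start", lineno, path)
    end0 <- .num_or_stop(getcol(3), "end", lineno, path)
    if (any(start0 >= end0))
      stop(sprintf("%s: line %d: start >= end", basename(path),
                   lineno[which(start0 >= end0)[1]]))
    name <- getcol(4)
    sumraw <- getcol(7)
    sumraw[!is.na(sumraw) & sumraw == "."] <- NA_character_
    summit0 <- .num_or_stop(sumraw, "summit", lineno, path)
    tags <- .num_or_stop(getcol(8), "tags", lineno, path)
    start1 <- start0 + 1; end1 <- end0; summit1 <- summit0 + 1
  } else {
    start1 <- .num_or_stop(getcol(2), "start", lineno, path)
    end1 <- .num_or_stop(getcol(3), "end", lineno, path)
    if (any(start1 > end1))
      stop(sprintf("%s: line %d: start > end", basename(path),
                   lineno[which(start1 > end1)[1]]))
    name <- sprintf("%s_macs_%d", condition, seq_along(chrom))
    summit1 <- start1 + .num_or_stop(getcol(5), "summit", lineno, path) - 1
    tags <- .num_or_stop(getcol(6), "tags", lineno, path)
    start0 <- start1 - 1
  }
  tags[is.na(tags)] <- 0
  bad <- which(tags < 0)
  if (length(bad))
    stop(sprintf("%s: line %d: negative tag count", basename(path),
                 lineno[bad[1]]))
  ok_sum <- !is.na(summit1) & (summit1 < start1 | summit1 > end1)
  if (any(ok_sum))
    stop(sprintf("%s: line %d: summit outside peak", basename(path),
                 lineno[which(ok_sum)[1]]))
  gr <- GRanges(chrom, IRanges(start1, end1),
                peak_id = ifelse(is.na(name) | name == ".",
                                 sprintf("%s_peak_%d", condition,
                                         seq_along(chrom)), name),
                summit = as.integer(summit1),
                raw_tags = tags)
  PeakSet(gr, condition, libraryDepth, referenceDepth)
}

#' Write peaks as BED6+2
#'
#' Writes a [PeakSet-class] in the `bed6plus` dialect read by [readPeaks()]:
#' 0-based half-open coordinates, columns
#' `chrom start end name score strand summit tags` with the raw tag count in
#' the last column and the 0-based absolute summit in column 7.
#'
#' @param peakset A `PeakSet`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writePeaks <- function(peakset, path) {
  gr <- peakRanges(peakset)
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = gr$peak_id, score = 0L, strand = ".",
                   summit = gr$summit - 1L, tags = gr$raw_tags)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

.gene_granges <- function(chrom, start1, end1, strand, gene_id, exons,
                          cds_start = NA_integer_, cds_end = NA_integer_) {
  gr <- GRanges(chrom, IRanges(start1, end1), strand = strand)
  gr$gene_id <- gene_id
  gr$exons <- exons
  gr$cds_start <- rep(as.integer(cds_start), length.out = length(gr))
  gr$cds_end <- rep(as.integer(cds_end), length.out = length(gr))
  bad <- any(vapply(seq_along(gr), function(i) {
    ex <- exons[[i]]
    length(ex) == 0L || min(start(ex)) < start1[i] || max(end(ex)) > end1[i]
  }, logical(1)))
  if (bad) stop("exon outside transcript bounds")
  gr
}

#' Read gene models
#'
#' Reads transcript models from BED12 or GTF into a `GRanges` of genes with
#' metadata columns `gene_id`, `exons` (an `IRangesList` in absolute
#' coordinates), and `cds_start`/`cds_end` (`NA` when the model is
#' non-coding). GTF 1-based closed coordinates and BED 0-based half-open
#' blocks are both converted to the internal 1-based closed convention.
#' When several transcripts share a `gene_id`, the longest transcript is
#' kept.
#'
#' The TSS of a gene is its `start` on `+` and its `end` on `-`; the TTS is
#' the opposite end (see [tssPosition()]).
#'
#' @param path Path to the gene model file.
#' @param dialect `"bed12"` or `"gtf"`.
#' @return `GRanges` of gene models.
#' @export
readGeneModels <- function(path, dialect = c("bed12", "gtf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "bed12") {
    b <- rtracklayer::import(path, format = "bed")
    if (is.null(b$blocks))
      b$blocks <- IRangesList(lapply(width(b), function(w) IRanges(1, w)))
    exons <- IRangesList(lapply(seq_along(b), function(i)
      shift(b$blocks[[i]], start(b)[i] - 1L)))
    thick <- b$thick
    # zero-width thick (thickStart == thickEnd in the file) means no CDS
    cs <- ifelse(width(thick) > 0, start(thick), NA_integer_)
    ce <- ifelse(width(thick) > 0, end(thick), NA_integer_)
    gr <- .gene_granges(as.character(seqnames(b)), start(b), end(b),
                        as.character(strand(b)), b$name, exons, cs, ce)
  } else {
    g <- rtracklayer::import(path, format = "gtf")
    ex <- g[g$type == "exon"]
    if (!length(ex)) stop("GTF contains no exon features")
    if (is.null(ex$transcript_id)) stop("GTF exons lack transcript_id")
    txid <- ex$transcript_id
    sp <- split(ex, txid)
    tx <- g[g$type == "transcript"]
    cds <- g[g$type == "CDS"]
    cds_by_tx <- if (length(cds)) split(cds, cds$transcript_id) else NULL
    ids <- names(sp)
    rows <- lapply(ids, function(id) {
      e <- sort(sp[[id]], ignore.strand = TRUE)
      ts <- min(start(e)); te <- max(end(e))
      if (length(tx) && id %in% tx$transcript_id) {
        t1 <- tx[tx$transcript_id == id][1]
        if (min(start(e)) < start(t1) || max(end(e)) > end(t1))
          stop("exon outside transcript bounds for ", id)
        ts <- start(t1); te <- end(t1)
      }
      cs <- NA_integer_; ce <- NA_integer_
      if (!is.null(cds_by_tx) && id %in% names(cds_by_tx)) {
        cc <- cds_by_tx[[id]]
        cs <- min(start(cc)); ce <- max(end(cc))
      }
      gid <- e$gene_id[1]
      if (is.null(gid) || is.na(gid)) gid <- id
      list(chrom = as.character(seqnames(e))[1], start = ts, end = te,
           strand = as.character(strand(e))[1], gene_id = gid,
           exons = ranges(e), cs = cs, ce = ce)
    })
    gr <- .gene_granges(
      vapply(rows, `[[`, character(1), "chrom"),
      vapply(rows, `[[`, numeric(1), "start"),
      vapply(rows, `[[`, numeric(1), "end"),
      vapply(rows, `[[`, character(1), "strand"),
      vapply(rows, `[[`, character(1), "gene_id"),
      IRangesList(lapply(rows, `[[`, "exons")),
      vapply(rows, `[[`, numeric(1), "cs"),
      vapply(rows, `[[`, numeric(1), "ce"))
  }
  # deduplicate by gene_id keeping the longest transcript
  if (anyDuplicated(gr$gene_id)) {
    o <- order(gr$gene_id, -width(gr))
    gr <- gr[o][!duplicated(gr$gene_id[o])]
  }
  sort(gr, ignore.strand = TRUE)
}

#' Write gene models as BED12
#'
#' @param genes `GRanges` of gene models as returned by [readGeneModels()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeGeneModels <- function(genes, path) {
  n <- length(genes)
  lines <- vapply(seq_len(n), function(i) {
    ex <- genes$exons[[i]]
    ex <- sort(ex)
    cs <- genes$cds_start[i]; ce <- genes$cds_end[i]
    thick0 <- if (is.na(cs)) c(start(genes)[i] - 1L, start(genes)[i] - 1L)
              else c(cs - 1L, ce)
    paste(as.character(seqnames(genes))[i], start(genes)[i] - 1L,
          end(genes)[i], genes$gene_id[i], 0L,
          as.character(strand(genes))[i], thick0[1], thick0[2], "0",
          length(ex), paste0(paste(width(ex), collapse = ","), ","),
          paste0(paste(start(ex) - start(genes)[i], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' TSS and TTS positions of gene models
#'
#' The transcription start site is the `start` of a `+` gene and the `end`
#' of a `-` gene; the termination site is the opposite end.
#'
#' @param genes `GRanges` of gene models.
#' @return Integer vector of 1-based positions.
#' @export
tssPosition <- function(genes) {
  ifelse(as.character(strand(genes)) == "-", end(genes), start(genes))
}

#' @rdname tssPosition
#' @export
ttsPosition <- function(genes) {
  ifelse(as.character(strand(genes)) == "-", start(genes), end(genes))
}

#' Read a per-gene expression table
#'
#' Reads a tab-separated table with header `gene_id LOW MID HIGH` holding
#' mean log2 intensities per condition. Linear fold changes are derived as
#' `fc_high_vs_mid = 2^(HIGH - MID)` and `fc_low_vs_mid = 2^(LOW - MID)`
#' (direction preserved as a ratio above or below 1).
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with columns `gene_id`, `LOW`, `MID`, `HIGH`,
#'   `fc_high_vs_mid`, `fc_low_vs_mid`.
#' @export
readExpression <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", .CONDITIONS)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("expression table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in expression table: ",
         df$gene_id[duplicated(df$gene_id)][1])
  for (cc in .CONDITIONS)
    if (!all(is.finite(df[[cc]])))
      stop("non-finite log2 values in column ", cc)
  df <- df[, need]
  df$fc_high_vs_mid <- 2^(df$HIGH - df$MID)
  df$fc_low_vs_mid <- 2^(df$LOW - df$MID)
  df
}

#' @rdname readExpression
#' @param expr Expression `data.frame` (only `gene_id`, `LOW`, `MID`,
#'   `HIGH` are written; fold changes are recomputed on read).
#' @export
writeExpression <- function(expr, path) {
  writeTable(expr[, c("gene_id", .CONDITIONS)], path)
}

#' Read / write a genome FASTA
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()]. Sequence names are truncated at the
#' first whitespace; lowercase bases are normalized to uppercase by the
#' DNA alphabet.
#'
#' @param path FASTA path.
#' @return `DNAStringSet` keyed by sequence name.
#' @export
readGenome <- function(path) {
  g <- readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' @rdname readGenome
#' @param genome A `DNAStringSet`.
#' @export
writeGenome <- function(genome, path) {
  writeXStringSet(genome, path)
  invisible(path)
}

#' Read / write result tables
#'
#' All result tables are TSV: tab-separated, header row, UTF-8, `.` decimal
#' separator, no quoting. `writeTable()` followed by `readTable()` is an
#' identity on data frames of character/numeric columns.
#'
#' @param x `data.frame` to write.
#' @param path File path.
#' @return `readTable()` returns a `data.frame`.
#' @export
writeTable <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeTable
#' @export
readTable <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
             fileEncoding = "UTF-8")
}
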