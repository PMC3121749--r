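#' PeakSet: one condition's called binding intervals
#'
#' A `PeakSet` holds the peak calls of a single signaling condition as a
#' [GenomicRanges::GRanges] with metadata columns `peak_id`, `summit`
#' (absolute 1-based coordinate), `raw_tags` (raw sequencing tag count) and
#' `enrichment` (depth-normalized tag count), together with the condition
#' label and sequencing depths. Enrichment is always
#' `raw_tags * referenceDepth / libraryDepth`, so peak heights are comparable
#' across libraries sequenced to different depths.
#'
#' Peaks of a `PeakSet` are sorted and mutually disjoint: overlapping
#' same-condition intervals are merged at construction time (tag counts
#' summed, the summit of the peak with more tags kept), which makes the
#' cross-condition union semantics of [mergeUnion()] well defined.
#'
#' @slot ranges `GRanges` of peak intervals with the metadata columns above.
#' @slot condition One of `"LOW"`, `"MID"`, `"HIGH"`.
#' @slot libraryDepth Total sequenced tags of the library (> 0).
#' @slot referenceDepth Depth to which enrichments are normalized
#'   (default 1e7, the lower bound of typical 10-13 million tag libraries).
#'
#' @seealso [readPeaks()], [mergeUnion()]
#' @export
setClass("PeakSet",
  representation(
    ranges = "GRanges",
    condition = "character",
    libraryDepth = "numeric",
    referenceDepth = "numeric"
  )
)

setValidity("PeakSet", function(object) {
  msg <- character()
  gr <- object@ranges
  if (!(length(object@condition) == 1L &&
        object@condition %in% .CONDITIONS))
    msg <- c(msg, "condition must be one of LOW, MID, HIGH")
  if (!(length(object@libraryDepth) == 1L && object@libraryDepth > 0))
    msg <- c(msg, "libraryDepth must be a single positive number")
  if (!(length(object@referenceDepth) == 1L && object@referenceDepth > 0))
    msg <- c(msg, "referenceDepth must be a single positive number")
  need <- c("peak_id", "summit", "raw_tags", "enrichment")
  if (!all(need %in% colnames(mcols(gr))))
    msg <- c(msg, paste("ranges must carry metadata columns",
                        paste(need, collapse = ", ")))
  if (length(gr)) {
    if (is.unsorted(order(as.factor(seqnames(gr)), start(gr))) ||
        !identical(gr, sort(gr, ignore.strand = TRUE)))
      msg <- c(msg, "peaks must be sorted by (chrom, start)")
    if (!isDisjoint(gr, ignore.strand = TRUE))
      msg <- c(msg, "peaks of one condition must not overlap")
    if (all(need %in% colnames(mcols(gr)))) {
      if (any(gr$raw_tags < 0)) msg <- c(msg, "raw_tags must be >= 0")
      if (any(gr$summit < start(gr) | gr$summit > end(gr)))
        msg <- c(msg, "summit must lie within its peak")
      sc <- object@referenceDepth / object@libraryDepth
      if (any(abs(gr$enrichment - gr$raw_tags * sc) > 1e-6))
        msg <- c(msg, "enrichment must equal raw_tags * depthScale")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PeakSet
#'
#' Builds a validated [PeakSet-class] from a `GRanges` of peak calls.
#' Peaks are sorted; overlapping same-condition peaks are merged (tags
#' summed, summit of the larger peak kept); missing summits default to the
#' interval midpoint; enrichment is (re)computed as
#' `raw_tags * referenceDepth / libraryDepth`.
#'
#' @param ranges `GRanges` with metadata column `raw_tags` and optionally
#'   `summit` (absolute 1-based) and `peak_id`.
#' @param condition Condition label, one of `"LOW"`, `"MID"`, `"HIGH"`.
#' @param libraryDepth Total sequenced tags of this library.
#' @param referenceDepth Normalization depth (default 1e7).
#' @return A [PeakSet-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200),
#'                              raw_tags = 40L)
#' PeakSet(gr, "MID", libraryDepth = 1e7)
#' @export
PeakSet <- function(ranges, condition, libraryDepth, referenceDepth = 1e7) {
  stopifnot(is(ranges, "GRanges"))
  if (is.null(ranges$raw_tags))
    stop("ranges must carry a 'raw_tags' metadata column")
  strand(ranges) <- "*"
  if (is.null(ranges$summit))
    ranges$summit <- NA_integer_
  na <- is.na(ranges$summit)
  ranges$summit[na] <- start(ranges)[na] + width(ranges)[na] %/% 2L
  ranges$summit <- as.integer(ranges$summit)
  if (is.null(ranges$peak_id))
    ranges$peak_id <- sprintf("%s_peak_%d", condition, seq_along(ranges))
  ranges <- GenomeInfoDb::sortSeqlevels(ranges)
  ranges <- sort(ranges, ignore.strand = TRUE)
  if (length(ranges) && !isDisjoint(ranges, ignore.strand = TRUE)) {
    red <- reduce(ranges, with.revmap = TRUE, ignore.strand = TRUE,
                  min.gapwidth = 0L)
    idx <- red$revmap
    tags <- vapply(idx, function(i) sum(ranges$raw_tags[i]), numeric(1))
    big <- vapply(idx, function(i) i[which.max(ranges$raw_tags[i])],
                  integer(1))
    red$revmap <- NULL
    red$peak_id <- ranges$peak_id[big]
    red$summit <- ranges$summit[big]
    red$raw_tags <- tags
    ranges <- red
  }
  ranges$raw_tags <- as.numeric(ranges$raw_tags)
  ranges$enrichment <- ranges$raw_tags * referenceDepth / libraryDepth
  mcols(ranges) <- mcols(ranges)[, c("peak_id", "summit", "raw_tags",
                                     "enrichment")]
  new("PeakSet", ranges = ranges, condition = condition,
      libraryDepth = as.numeric(libraryDepth),
      referenceDepth = as.numeric(referenceDepth))
}

#' @describeIn PeakSet-class number of peaks
#' @param x,object A `PeakSet`.
#' @export
setMethod("length", "PeakSet", function(x) length(x@ranges))

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet of", length(object), "peaks |", object@condition,
      "| library depth", format(object@libraryDepth, big.mark = ","),
      "| depth scale", signif(depthScale(object), 4), "\n")
  if (length(object)) show(utils::head(object@ranges, 3))
})

#' SimulationConfig: parameters of the synthetic peak-landscape study
#'
#' Holds every tunable of the synthetic-data generator: genome geometry,
#' gene and binding-site numbers, the mixture over dose-response binding
#' modes with per-mode expected normalized enrichments, per-condition library
#' depths, the genomic-feature placement bias, motif planting, and the
#' coupling of expression fold changes to responsive binding. Defaults
#' emulate the study conditions of a three-condition ChIP-Seq experiment:
#' libraries of 10-13 million tags, thousands of sites, a >12-tag emission
#' floor, and a 1.5-fold expression coupling. See [simulationConfig()].
#'
#' @slot seed,nChroms,chromLength,nGenes,nSites Geometry and scale.
#' @slot modeMixture Named probability vector over the four planted modes.
#' @slot modeMeans 4x3 matrix of expected normalized enrichments
#'   (rows = modes, columns = LOW/MID/HIGH).
#' @slot depthTriple Per-condition library depths.
#' @slot featureBias Named probability vector over placement categories
#'   `promoter`, `exon`, `intron`, `distal`, `desert`.
#' @slot motifPlantRate,motifSequences Motif planting at site centers.
#' @slot exprCoupling,exprNoiseSd,deConcordance Expression generator.
#' @slot emitFloor Raw-tag floor below which a condition's peak is not
#'   emitted (strict >, default 12).
#' @slot peakWidthRange Range of site widths in bp.
#' @slot testMode If `TRUE`, Poisson draws are replaced by their means for
#'   exact downstream assertions.
#' @export
setClass("SimulationConfig",
  representation(
    seed = "integer", nChroms = "integer", chromLength = "integer",
    nGenes = "integer", nSites = "integer",
    modeMixture = "numeric", modeMeans = "matrix",
    depthTriple = "numeric", featureBias = "numeric",
    motifPlantRate = "numeric", motifSequences = "character",
    exprCoupling = "numeric", exprNoiseSd = "numeric",
    deConcordance = "numeric", emitFloor = "numeric",
    peakWidthRange = "integer", testMode = "logical"
  )
)

.SIM_MODES <- c("GRADED", "LOW_DOMINANT", "HIGH_DOMINANT", "INVARIANT")
.PLACEMENTS <- c("promoter", "exon", "intron", "distal", "desert")

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (abs(sum(object@modeMixture) - 1) > 1e-8 ||
      !identical(names(object@modeMixture), .SIM_MODES))
    msg <- c(msg, "modeMixture must be a probability vector over the four modes")
  if (abs(sum(object@featureBias) - 1) > 1e-8 ||
      !identical(names(object@featureBias), .PLACEMENTS))
    msg <- c(msg,
      "featureBias must be a probability vector over placement categories")
  if (!identical(rownames(object@modeMeans), .SIM_MODES) ||
      !identical(colnames(object@modeMeans), .CONDITIONS))
    msg <- c(msg, "modeMeans must be a 4x3 matrix (modes x conditions)")
  if (!identical(names(object@depthTriple), .CONDITIONS) ||
      any(object@depthTriple <= 0))
    msg <- c(msg, "depthTriple must be positive and named LOW/MID/HIGH")
  if (object@motifPlantRate < 0 || object@motifPlantRate > 1)
    msg <- c(msg, "motifPlantRate must be in [0, 1]")
  if (any(!grepl("^[ACGT]+$", object@motifSequences)))
    msg <- c(msg, "motifSequences must be ACGT strings")
  if (object@exprCoupling <= 1)
    msg <- c(msg, "exprCoupling must exceed 1")
  if (object@deConcordance <= 0 || object@deConcordance > 1)
    msg <- c(msg, "deConcordance must be in (0, 1]")
  if (length(object@peakWidthRange) != 2L ||
      object@peakWidthRange[1] > object@peakWidthRange[2])
    msg <- c(msg, "peakWidthRange must be an increasing pair")
  # mode means must respect their mode's inequalities with margin >= 2x the
  # classification thresholds (f = 1.5, r = 1.25), so Poisson noise cannot
  # push sites across mode boundaries in bulk
  mm <- object@modeMeans
  f2 <- 2 * 1.5; r2 <- 2 * 1.25
  g <- mm["GRADED", ]
  if (!(g["HIGH"] >= g["MID"] && g["MID"] >= g["LOW"] &&
        g["HIGH"] / g["LOW"] >= f2 && g["HIGH"] / g["MID"] >= r2 &&
        g["MID"] / g["LOW"] >= r2))
    msg <- c(msg, "GRADED means violate the graded inequalities with 2x margin")
  l <- mm["LOW_DOMINANT", ]
  if (!(l["LOW"] / max(l["MID"], l["HIGH"]) >= f2))
    msg <- c(msg, "LOW_DOMINANT means lack a 2x dominance margin")
  h <- mm["HIGH_DOMINANT", ]
  if (!(h["HIGH"] / max(h["MID"], h["LOW"]) >= f2) ||
      max(h["LOW"], h["MID"]) / min(h["LOW"], h["MID"]) >= 1.25)
    msg <- c(msg,
      "HIGH_DOMINANT means need a 2x dominance margin and flat LOW/MID")
  i <- mm["INVARIANT", ]
  if (max(i) / min(i) >= 1.25)
    msg <- c(msg, "INVARIANT means must be flat (max/min < 1.25)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nChroms, "chrom x",
      format(object@chromLength, big.mark = ","), "bp |",
      object@nGenes, "genes |", object@nSites, "sites | seed",
      object@seed, if (object@testMode) "| test mode (noise-free)" else "",
      "\n")
  cat("  mode mixture:",
      paste(sprintf("%s=%.2f", names(object@modeMixture),
                    object@modeMixture), collapse = " "), "\n")
  cat("  feature bias:",
      paste(sprintf("%s=%.2f", names(object@featureBias),
                    object@featureBias), collapse = " "), "\n")
})
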