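#' @name PeakSet-accessors
#' @title Accessors for PeakSet objects
#' @description Extract the peak ranges, condition label and depth
#'   information from a [PeakSet-class].
#' @param object A `PeakSet`.
#' @return `peakRanges()` the `GRanges` of peaks; `condition()` the condition
#'   label; `libraryDepth()`/`referenceDepth()` the depths;
#'   `depthScale()` their ratio `referenceDepth / libraryDepth`.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200),
#'                              raw_tags = 26L)
#' ps <- PeakSet(gr, "HIGH", libraryDepth = 1.3e7)
#' depthScale(ps)
#' peakRanges(ps)$enrichment
NULL

#' @rdname PeakSet-accessors
#' @export
setGeneric("peakRanges", function(object) standardGeneric("peakRanges"))
#' @rdname PeakSet-accessors
#' @export
setMethod("peakRanges", "PeakSet", function(object) object@ranges)

#' @rdname PeakSet-accessors
#' @export
setGeneric("condition", function(object) standardGeneric("condition"))
#' @rdname PeakSet-accessors
#' @export
setMethod("condition", "PeakSet", function(object) object@condition)

#' @rdname PeakSet-accessors
#' @export
setGeneric("libraryDepth", function(object) standardGeneric("libraryDepth"))
#' @rdname PeakSet-accessors
#' @export
setMethod("libraryDepth", "PeakSet", function(object) object@libraryDepth)

#' @rdname PeakSet-accessors
#' @export
setGeneric("referenceDepth",
           function(object) standardGeneric("referenceDepth"))
#' @rdname PeakSet-accessors
#' @export
setMethod("referenceDepth", "PeakSet",
          function(object) object@referenceDepth)

#' @rdname PeakSet-accessors
#' @export
setGeneric("depthScale", function(object) standardGeneric("depthScale"))
#' @rdname PeakSet-accessors
#' @export
setMethod("depthScale", "PeakSet",
          function(object) object@referenceDepth / object@libraryDepth)
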