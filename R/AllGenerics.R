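# Accessor generics. Slots are never accessed with @ by user code.

#' Accessors for shallowNIPT classes
#'
#' Small accessor family: \code{bins()} returns the bin \code{GRanges} of a
#' \code{BinGrid}; \code{binSize()} its bin width; \code{binGrid()} the grid
#' carried by a derived object; \code{sampleID()} the sample identifier;
#' \code{readCounts()} the per-bin count vector of a \code{BinCounts};
#' \code{blacklistedBins()} the logical blacklist of a \code{ReferencePanel};
#' \code{regions()} the \code{GRanges} of a \code{RegionSet}.
#'
#' @param x an object of the documented classes.
#' @return see description.
#' @name accessors
#' @aliases bins binSize binGrid sampleID readCounts blacklistedBins regions
#' @examples
#' grid <- makeBins(genomeBuild("toy", c(chr1 = 3e6)), 1e6)
#' binSize(grid)
#' length(bins(grid))
NULL

#' @rdname accessors
#' @export
setGeneric("bins", function(x) standardGeneric("bins"))
#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @rdname accessors
#' @export
setGeneric("binGrid", function(x) standardGeneric("binGrid"))
#' @rdname accessors
#' @export
setGeneric("sampleID", function(x) standardGeneric("sampleID"))
#' @rdname accessors
#' @export
setGeneric("readCounts", function(x) standardGeneric("readCounts"))
#' @rdname accessors
#' @export
setGeneric("blacklistedBins", function(x) standardGeneric("blacklistedBins"))
#' @rdname accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname accessors
setMethod("bins", "BinGrid", function(x) x@bins)
#' @rdname accessors
setMethod("binSize", "BinGrid", function(x) x@binSize)
#' @rdname accessors
setMethod("binGrid", "BinCounts", function(x) x@grid)
#' @rdname accessors
setMethod("binGrid", "ReferencePanel", function(x) x@grid)
#' @rdname accessors
setMethod("binGrid", "SampleProfile", function(x) x@grid)
#' @rdname accessors
setMethod("sampleID", "BinCounts", function(x) x@sampleID)
#' @rdname accessors
setMethod("sampleID", "SampleProfile", function(x) x@sampleID)
#' @rdname accessors
setMethod("readCounts", "BinCounts", function(x) x@counts)
#' @rdname accessors
setMethod("blacklistedBins", "ReferencePanel", function(x) x@blacklist)
#' @rdname accessors
setMethod("regions", "RegionSet", function(x) x@regions)
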