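#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomeInfoDb Seqinfo seqinfo seqlevels seqlengths seqnames<-
NULL

#' BinGrid: the binned coordinate backbone
#'
#' An ordered set of fixed-width genomic bins tiling a genome build, carrying
#' per-bin GC content and a usability flag. All counting, normalization and
#' calling in the package is expressed on a \code{BinGrid}; two objects are
#' comparable only when their grids are identical.
#'
#' Bins are 0-based half-open internally and tile each chromosome without gaps
#' or overlaps; the last bin of a chromosome may be shorter than
#' \code{binSize}. The underlying \code{GRanges} (1-based, as usual for
#' Bioconductor) carries metadata columns \code{gc} (fraction in [0,1], may be
#' \code{NA}) and \code{usable} (logical).
#'
#' @slot bins a \code{GRanges} of bins with mcols \code{gc} and \code{usable}.
#' @slot binSize integer bin width in bp.
#' @seealso [makeBins()], [annotateGC()]
#' @export
setClass("BinGrid", slots = c(bins = "GRanges", binSize = "integer"))

setValidity("BinGrid", function(object) {
  b <- object@bins
  if (length(object@binSize) != 1L || is.na(object@binSize) ||
      object@binSize < 1L)
    return("binSize must be a single positive integer")
  if (!all(c("gc", "usable") %in% colnames(mcols(b))))
    return("bins must carry 'gc' and 'usable' metadata columns")
  sl <- seqlengths(seqinfo(b))
  if (any(is.na(sl)))
    return("all chromosomes must have known lengths (seqlengths)")
  # tiling: per chromosome, starts are 1, 1+w, 1+2w, ... and last end = length
  for (chr in seqlevels(b)) {
    idx <- which(as.character(seqnames(b)) == chr)
    if (length(idx) == 0L) return(sprintf("chromosome %s has no bins", chr))
    s <- start(b)[idx]; e <- end(b)[idx]
    w <- as.integer(object@binSize)
    n <- length(idx)
    exp_s <- seq.int(1L, by = w, length.out = n)
    if (!identical(as.integer(s), exp_s))
      return(sprintf("bins do not tile chromosome %s", chr))
    if (e[n] != sl[[chr]] || any(e[-n] != s[-n] + w - 1L))
      return(sprintf("bin ends do not tile chromosome %s", chr))
  }
  g <- mcols(b)$gc
  if (any(!is.na(g) & (g < 0 | g > 1))) return("gc must lie in [0,1]")
  TRUE
})

#' RegionSet: a named collection of labelled genomic regions
#'
#' Used for the seven chrY marker genes and for the pseudoautosomal regions
#' (PAR1/PAR2). Labels are unique within a set.
#'
#' @slot name set name.
#' @slot regions a \code{GRanges} with an mcol \code{label}.
#' @seealso [loadRegions()], [chrYGeneRegions()], [parRegions()]
#' @export
setClass("RegionSet", slots = c(name = "character", regions = "GRanges"))

setValidity("RegionSet", function(object) {
  lab <- mcols(object@regions)$label
  if (length(object@regions) > 0 && is.null(lab))
    return("regions must carry a 'label' metadata column")
  if (anyDuplicated(lab)) return("region labels must be unique within a set")
  TRUE
})

#' BinCounts: one sample's raw per-bin read counts
#'
#' Raw (uncorrected) read counts of one sample on a \code{BinGrid}, together
#' with the counting metadata needed to reproduce them. \code{totalHQReads} is
#' the genome-wide number of primary mapped reads passing the MAPQ cutoff,
#' including reads on contigs outside the grid, and is the denominator of the
#' chrY sex statistic; consequently \code{sum(counts) <= totalHQReads}.
#'
#' @slot sampleID sample identifier.
#' @slot grid the \code{BinGrid} the counts live on.
#' @slot counts numeric vector of non-negative counts, one per bin.
#' @slot totalHQReads total high-quality primary mapped reads.
#' @slot mapqMin MAPQ cutoff used.
#' @slot dedupPositions whether position-level duplicates were collapsed.
#' @export
setClass("BinCounts",
  slots = c(sampleID = "character", grid = "BinGrid", counts = "numeric",
            totalHQReads = "numeric", mapqMin = "numeric",
            dedupPositions = "logical"))

setValidity("BinCounts", function(object) {
  if (length(object@counts) != length(object@grid@bins))
    return("length(counts) must equal the number of bins")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (sum(object@counts) > object@totalHQReads + 1e-6)
    return("sum(counts) cannot exceed totalHQReads")
  TRUE
})

#' RegionCounts: per-label read counts over a RegionSet
#'
#' @slot sampleID sample identifier.
#' @slot setName name of the \code{RegionSet} counted.
#' @slot counts named numeric vector, one entry per region label.
#' @slot denominator context-dependent denominator (e.g. all chrY reads for
#'   the chrY gene statistic).
#' @export
setClass("RegionCounts",
  slots = c(sampleID = "character", setName = "character",
            counts = "numeric", denominator = "numeric"))

#' ReferencePanel: location/scale statistics from healthy pregnancies
#'
#' Per-bin mean/SD of GC-corrected normalized depth and per-chromosome
#' mean/SD of chromosome fractions, estimated from a set of confirmed-normal
#' (euploid female) pregnancy samples. Bins that are unusable, zero-inflated
#' or variance-degenerate are blacklisted and excluded from all downstream
#' statistics. The panel also stores the female chrY background statistics
#' and the per-Y-copy calibration constant \code{cY1} used by the
#' sex-chromosome-aneuploidy classifier and the chrY fetal-fraction estimator.
#'
#' @slot grid the shared \code{BinGrid}.
#' @slot nSamples number of panel samples.
#' @slot binMean,binSD per-bin statistics of GC-corrected normalized depth.
#' @slot blacklist logical vector, \code{TRUE} for excluded bins.
#' @slot chromStats data.frame with columns \code{chrom}, \code{meanFrac},
#'   \code{sdFrac}: chromosome fractions of autosomal binned reads.
#' @slot yMean,ySD female chrY fraction (of total binned reads) background.
#' @slot geneYMean,geneYSD female chrY-gene-region fraction background.
#' @slot cY1 expected chrY y-statistic per fetal Y copy at fetal fraction 1.
#' @slot usable whether the panel is usable (some bins not blacklisted).
#' @seealso [buildPanel()], [profileSample()]
#' @export
setClass("ReferencePanel",
  slots = c(grid = "BinGrid", nSamples = "integer",
            binMean = "numeric", binSD = "numeric", blacklist = "logical",
            chromStats = "data.frame",
            yMean = "numeric", ySD = "numeric",
            geneYMean = "numeric", geneYSD = "numeric",
            cY1 = "numeric", usable = "logical"))

setValidity("ReferencePanel", function(object) {
  nb <- length(object@grid@bins)
  if (length(object@binMean) != nb || length(object@binSD) != nb ||
      length(object@blacklist) != nb)
    return("per-bin statistics must match the grid length")
  if (object@nSamples < 2L) return("a reference panel needs >= 2 samples")
  if (any(object@binSD < 0, na.rm = TRUE)) return("binSD must be >= 0")
  TRUE
})

#' SampleProfile: a sample's normalized profile versus a panel
#'
#' GC-corrected normalized depth per bin, log2(observed/expected) versus the
#' panel per-bin mean, and per-bin z-scores. Blacklisted bins carry \code{NA}.
#'
#' @slot sampleID sample identifier.
#' @slot grid the shared \code{BinGrid}.
#' @slot depth GC-corrected normalized depth per bin.
#' @slot log2Ratio per-bin log2(observed/expected).
#' @slot z per-bin z-score versus panel mean/SD.
#' @export
setClass("SampleProfile",
  slots = c(sampleID = "character", grid = "BinGrid", depth = "numeric",
            log2Ratio = "numeric", z = "numeric"))

#' FFRegressionModel: elastic-net fetal-fraction regressor
#'
#' Linear model from GC-corrected normalized autosomal bin depths to fetal
#' fraction, trained by elastic net on samples of known fetal fraction.
#'
#' @slot intercept model intercept.
#' @slot weights per-bin weights, one per usable autosomal bin.
#' @slot binIndex indices (into the grid) of the bins carrying weights.
#' @slot grid the \code{BinGrid} the model was trained on.
#' @slot meta training metadata (n, seed, penalty mixing alpha, lambda).
#' @export
setClass("FFRegressionModel",
  slots = c(intercept = "numeric", weights = "numeric", binIndex = "integer",
            grid = "BinGrid", meta = "list"))

setValidity("FFRegressionModel", function(object) {
  if (length(object@weights) != length(object@binIndex))
    return("weights and binIndex must have equal length")
  TRUE
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "BinGrid", function(object) {
  cat(sprintf("BinGrid: %d bins of %s bp on %d chromosome(s) [%s]\n",
              length(object@bins), format(object@binSize, big.mark = ","),
              length(seqlevels(object@bins)),
              GenomeInfoDb::genome(seqinfo(object@bins))[1]))
  cat(sprintf("  usable bins: %d; GC annotated: %s\n",
              sum(mcols(object@bins)$usable),
              ifelse(all(is.na(mcols(object@bins)$gc)), "no", "yes")))
})

setMethod("show", "RegionSet", function(object) {
  cat(sprintf("RegionSet '%s': %d region(s)\n", object@name,
              length(object@regions)))
  if (length(object@regions))
    cat(" ", paste(mcols(object@regions)$label, collapse = ", "), "\n")
})

setMethod("show", "BinCounts", function(object) {
  cat(sprintf("BinCounts for sample '%s': %s binned / %s total HQ reads\n",
              object@sampleID,
              format(sum(object@counts), big.mark = ","),
              format(object@totalHQReads, big.mark = ",")))
  cat(sprintf("  grid: %d bins of %s bp; MAPQ >= %d; position dedup: %s\n",
              length(object@grid@bins),
              format(object@grid@binSize, big.mark = ","),
              as.integer(object@mapqMin), object@dedupPositions))
})

setMethod("show", "ReferencePanel", function(object) {
  cat(sprintf("ReferencePanel: %d samples, %d bins (%d blacklisted)%s\n",
              object@nSamples, length(object@grid@bins),
              sum(object@blacklist),
              if (object@usable) "" else " [UNUSABLE]"))
})

setMethod("show", "SampleProfile", function(object) {
  ok <- !is.na(object@z)
  cat(sprintf("SampleProfile '%s': %d bins (%d informative)\n",
              object@sampleID, length(object@z), sum(ok)))
  if (any(ok))
    cat(sprintf("  z: mean %.3f sd %.3f; log2 ratio range [%.3f, %.3f]\n",
                mean(object@z[ok]), stats::sd(object@z[ok]),
                min(object@log2Ratio[ok]), max(object@log2Ratio[ok])))
})

setMethod("show", "FFRegressionModel", function(object) {
  cat(sprintf(
    "FFRegressionModel: %d bins, %d nonzero weights (alpha %.2f, n = %d)\n",
    length(object@weights), sum(object@weights != 0),
    object@meta$alpha, object@meta$n))
})
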