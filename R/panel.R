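.sameGrid <- function(g1, g2) {
  identical(binSize(g1), binSize(g2)) &&
    length(bins(g1)) == length(bins(g2)) &&
    identical(as.character(seqnames(bins(g1))),
              as.character(seqnames(bins(g2)))) &&
    identical(start(bins(g1)), start(bins(g2)))
}

#' GC-correct a sample's binned counts
#'
#' Converts raw bin counts to normalized depths (count divided by the
#' autosomal binned total) and removes the smooth dependence of depth on bin
#' GC content. The GC trend is a local regression (lowess, span 0.3 by
#' default) of depth on GC over usable autosomal bins; every bin, including
#' the sex chromosomes, is divided by the trend value at its GC, so that
#' fetal dosage signal on chrX/chrY is preserved. Corrected depths are
#' rescaled so their mean over usable autosomal bins equals the raw mean.
#'
#' @param bc a [BinCounts-class] whose grid has GC annotation.
#' @param span lowess span (default 0.3).
#' @param minBins minimum usable autosomal bins with GC (default 50).
#' @return numeric vector of corrected normalized depths, one per bin.
#' @export
gcCorrect <- function(bc, span = 0.3, minBins = 50) {
  grid <- binGrid(bc)
  b <- bins(grid)
  cnt <- readCounts(bc)
  if (sum(cnt) <= 0) stop("all-zero counts")
  if (sum(cnt > 0) < 2) stop("degenerate depth distribution: ",
                             "fewer than two nonzero bins")
  gc <- mcols(b)$gc
  if (all(is.na(gc))) stop("GC missing on all bins; run annotateGC first")
  auto <- .autosomeBins(grid)
  denom <- sum(cnt[auto])
  if (denom <= 0) stop("no autosomal reads")
  depth <- cnt / denom
  fitIdx <- which(auto & mcols(b)$usable & !is.na(gc))
  if (length(fitIdx) < minBins)
    stop("need >= ", minBins, " usable autosomal bins with GC")
  lw <- stats::lowess(gc[fitIdx], depth[fitIdx], f = span)
  med <- stats::median(lw$y)
  if (!is.finite(med) || med <= 0) stop("degenerate GC trend fit")
  trend <- stats::approx(lw$x, lw$y, xout = gc, rule = 2, ties = mean)$y
  trend[is.na(trend)] <- med      # bins without GC: no correction applied
  trend <- pmax(trend, 0.05 * med)
  corrected <- depth / trend
  scale <- mean(depth[fitIdx]) / mean(corrected[fitIdx])
  corrected * scale
}

#' Build a reference panel from healthy-pregnancy samples
#'
#' Estimates the per-bin mean and SD of GC-corrected normalized depth and the
#' per-chromosome mean and SD of chromosome fractions (autosomal denominator)
#' across a set of confirmed-normal pregnancy samples, the benchmark against
#' which test samples are z-scored. Bins are blacklisted when flagged
#' unusable on the grid, when zero in more than \code{zeroFracMax} of panel
#' samples, or when their panel SD is zero. The panel also records the female
#' chrY background: the chrY read fraction (\code{yMean}/\code{ySD}) and,
#' when \code{regions} is supplied, the chrY-gene-region fraction
#' (\code{geneYMean}/\code{geneYSD}), both with PAR-overlapping bins excluded.
#'
#' @param samples list of [BinCounts-class], all on the same grid.
#' @param regions optional [RegionSet-class] of chrY marker genes.
#' @param exclude optional [RegionSet-class] masked in the gene statistic
#'   (default: the GRCh37 pseudoautosomal regions when the grid has a chrY).
#' @param span lowess span for GC correction.
#' @param zeroFracMax zero-inflation blacklist threshold (default 0.1).
#' @param cY1 calibration constant: expected chrY y-statistic per fetal Y
#'   copy at fetal fraction 1 (default [defaultCY1()]); stored for the SCA
#'   classifier and the chrY fetal-fraction estimator.
#' @return a [ReferencePanel-class].
#' @export
buildPanel <- function(samples, regions = NULL, exclude = NULL, span = 0.3,
                       zeroFracMax = 0.1, cY1 = defaultCY1()) {
  if (length(samples) < 2) stop("a reference panel needs >= 2 samples")
  grid <- binGrid(samples[[1]])
  for (s in samples[-1])
    if (!.sameGrid(binGrid(s), grid)) stop("grid mismatch between samples")
  depths <- vapply(samples, gcCorrect, numeric(length(bins(grid))),
                   span = span)
  binMean <- rowMeans(depths)
  binSD <- apply(depths, 1, stats::sd)
  rawZero <- vapply(samples, function(s) readCounts(s) == 0,
                    logical(length(bins(grid))))
  zeroFrac <- rowMeans(rawZero)
  blacklist <- !mcols(bins(grid))$usable | zeroFrac > zeroFracMax |
    binSD == 0
  fr <- vapply(samples, chromFractions, denominator = "autosomal",
               FUN.VALUE = numeric(length(seqlevels(bins(grid)))))
  if (is.null(dim(fr)))
    fr <- matrix(fr, nrow = 1,
                 dimnames = list(seqlevels(bins(grid)), NULL))
  chromStats <- data.frame(chrom = rownames(fr),
                           meanFrac = rowMeans(fr),
                           sdFrac = apply(fr, 1, stats::sd),
                           row.names = NULL)
  ybins <- .chrYBins(grid)
  yMean <- NA_real_; ySD <- NA_real_
  geneYMean <- NA_real_; geneYSD <- NA_real_
  if (any(ybins)) {
    yfrac <- vapply(samples, function(s)
      sum(readCounts(s)[ybins]) / sum(readCounts(s)), 0)
    yMean <- mean(yfrac); ySD <- stats::sd(yfrac)
    if (!is.null(regions) && length(regions(regions)) > 0) {
      if (is.null(exclude)) exclude <- tryCatch(parRegions(),
                                                error = function(e) NULL)
      gfrac <- vapply(samples, function(s) {
        rc <- regionCountsFromBins(s, regions, exclude = exclude)
        regionUnionCount(rc) / sum(readCounts(s))
      }, 0)
      geneYMean <- mean(gfrac); geneYSD <- stats::sd(gfrac)
    }
  }
  new("ReferencePanel", grid = grid, nSamples = length(samples),
      binMean = binMean, binSD = binSD, blacklist = blacklist,
      chromStats = chromStats, yMean = yMean, ySD = ySD,
      geneYMean = geneYMean, geneYSD = geneYSD, cY1 = cY1,
      usable = !all(blacklist))
}

#' Normalize a sample against a reference panel
#'
#' Computes the sample's GC-corrected normalized depth, the per-bin
#' log2(observed/expected) ratio against the panel mean, and the per-bin
#' z-score against the panel mean and SD. Blacklisted bins carry \code{NA}.
#' Because depths are fraction-normalized, a uniform sequencing-depth change
#' leaves log2 ratios and z-scores unchanged.
#'
#' @param bc a [BinCounts-class] on the panel's grid.
#' @param panel a [ReferencePanel-class].
#' @param span lowess span for GC correction (match the panel's).
#' @return a [SampleProfile-class].
#' @export
profileSample <- function(bc, panel, span = 0.3) {
  if (!.sameGrid(binGrid(bc), binGrid(panel)))
    stop("grid mismatch between sample and panel")
  if (!panel@usable) stop("reference panel is unusable (all bins blacklisted)")
  depth <- gcCorrect(bc, span = span)
  bl <- blacklistedBins(panel)
  l2 <- ifelse(bl, NA_real_, log2(depth / panel@binMean))
  z <- ifelse(bl, NA_real_, (depth - panel@binMean) / panel@binSD)
  new("SampleProfile", sampleID = sampleID(bc), grid = binGrid(bc),
      depth = depth, log2Ratio = l2, z = z)
}
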