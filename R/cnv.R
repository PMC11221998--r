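#' Segment a chromosome's bin profile into regions of equal copy number
#'
#' Recursive interval segmentation on per-bin z-scores (circular-binary-
#' segmentation style): at each step the sub-interval whose mean z differs
#' most from the rest of the current segment is found, scored by the
#' two-sample statistic
#' \eqn{T = (\bar z_{in} - \bar z_{out}) / \sqrt{1/n_{in} + 1/n_{out}}},
#' and accepted as a boundary pair when \eqn{|T| \ge} \code{splitZ}. The
#' procedure recurses into the resulting pieces and stops otherwise, so the
#' returned segments are contiguous and exhaustive over the chromosome's
#' informative (non-blacklisted) bins. A segment must contain at least
#' \code{minSegBins} bins.
#'
#' A focal event's boundaries are recovered exactly when its per-bin signal
#' is well above the bin noise; at marginal signal-to-noise the boundary
#' bins are intrinsically ambiguous.
#'
#' @param profile a [SampleProfile-class].
#' @param chrom chromosome to segment.
#' @param splitZ split acceptance threshold (default 5).
#' @param minSegBins minimum bins per candidate interval (default 2).
#' @return data.frame with one row per segment: \code{chrom}, \code{start},
#'   \code{end} (0-based half-open genomic), \code{nBins}, \code{meanLog2},
#'   \code{zSegment} (Stouffer over member bins).
#' @export
segmentBins <- function(profile, chrom, splitZ = 5, minSegBins = 2) {
  b <- bins(binGrid(profile))
  onChrom <- which(as.character(seqnames(b)) == chrom)
  if (length(onChrom) == 0) stop("no bins on ", chrom)
  info <- onChrom[!is.na(profile@z[onChrom])]
  if (length(info) == 0) stop("empty profile on ", chrom)
  z <- profile@z[info]
  l2 <- profile@log2Ratio[info]
  n <- length(z)

  best <- function(lo, hi) {
    # best sub-interval [i,j] of z[lo:hi] vs its complement within [lo,hi]
    zz <- z[lo:hi]; m <- length(zz)
    cs <- c(0, cumsum(zz)); S <- cs[m + 1]
    bestT <- 0; bestI <- NA; bestJ <- NA
    for (L in seq(minSegBins, m - minSegBins)) {
      s <- cs[(L + 1):(m + 1)] - cs[1:(m - L + 1)]
      Tt <- (s / L - (S - s) / (m - L)) / sqrt(1 / L + 1 / (m - L))
      k <- which.max(abs(Tt))
      if (abs(Tt[k]) > abs(bestT)) {
        bestT <- Tt[k]; bestI <- lo + k - 1; bestJ <- lo + k - 1 + L - 1
      }
    }
    list(T = bestT, i = bestI, j = bestJ)
  }

  segs <- list()
  recurse <- function(lo, hi) {
    m <- hi - lo + 1
    if (m >= 2 * minSegBins) {
      bb <- best(lo, hi)
      if (!is.na(bb$i) && abs(bb$T) >= splitZ &&
          !(bb$i == lo && bb$j == hi)) {
        if (bb$i > lo) recurse(lo, bb$i - 1)
        recurse(bb$i, bb$j)
        if (bb$j < hi) recurse(bb$j + 1, hi)
        return(invisible())
      }
    }
    segs[[length(segs) + 1]] <<- c(lo, hi)
    invisible()
  }
  recurse(1, n)
  segs <- segs[order(vapply(segs, `[`, 0, 1))]
  out <- do.call(rbind, lapply(segs, function(s) {
    idx <- info[s[1]:s[2]]
    data.frame(chrom = chrom,
               start = start(b)[idx[1]] - 1L,
               end = end(b)[idx[length(idx)]],
               nBins = length(idx),
               meanLog2 = mean(l2[s[1]:s[2]]),
               zSegment = sum(z[s[1]:s[2]]) / sqrt(s[2] - s[1] + 1))
  }))
  rownames(out) <- NULL
  out
}

#' Call copy-number variant segments
#'
#' Filters segments to reportable CNVs: a segment is reported when its size
#' is at least \code{minSizeMb} megabases and its Stouffer z magnitude is at
#' least \code{zThreshold}; the sign of the mean log2 ratio determines
#' duplication versus deletion. Each call is annotated with the expected
#' log2 magnitude of a single-copy fetal event at the given fetal fraction
#' (\eqn{\log_2(1 + f/2)} for gains, \eqn{\log_2(1 - f/2)} for losses);
#' segments whose magnitude is on the maternal heterozygous scale
#' (|mean log2| in [0.58, 1]) are additionally annotated "possibly maternal",
#' since a maternal CNV is carried by the whole cfDNA pool.
#'
#' @param segments data.frame from [segmentBins()] (rows from several
#'   chromosomes may be concatenated).
#' @param ff fetal fraction in (0, 1].
#' @param minSizeMb minimum reportable size (default 1 Mb).
#' @param zThreshold minimum |Stouffer z| (default 3).
#' @return data.frame of calls: \code{chrom}, \code{start}, \code{end},
#'   \code{nBins}, \code{meanLog2}, \code{zSegment}, \code{type}
#'   (dup/del), \code{sizeMb}, \code{expectedLog2}, \code{note}.
#' @export
callSegments <- function(segments, ff, minSizeMb = 1.0, zThreshold = 3) {
  stopifnot(ff > 0, ff <= 1)
  sizeMb <- (segments$end - segments$start) / 1e6
  keep <- sizeMb >= minSizeMb & abs(segments$zSegment) >= zThreshold
  out <- segments[keep, , drop = FALSE]
  sizeMb <- sizeMb[keep]
  if (nrow(out) == 0) {
    out <- cbind(out, type = character(0), sizeMb = numeric(0),
                 expectedLog2 = numeric(0), note = character(0))
    return(out)
  }
  type <- ifelse(out$meanLog2 > 0, "dup", "del")
  expectedLog2 <- ifelse(type == "dup", log2(.dosage(3, ff)),
                         log2(.dosage(1, ff)))
  note <- ifelse(abs(out$meanLog2) >= 0.58 & abs(out$meanLog2) <= 1,
                 "possibly maternal", "")
  out <- cbind(out, type = type, sizeMb = sizeMb,
               expectedLog2 = expectedLog2, note = note)
  rownames(out) <- NULL
  out
}
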