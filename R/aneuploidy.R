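#' Whole-chromosome fraction z-score
#'
#' The chromosome-fraction statistic: the sample's fraction of (autosomal)
#' binned reads on a chromosome, z-scored against the panel's per-chromosome
#' mean and SD. This is the whole-chromosome analogue of comparing the
#' percentage of reads on a chromosome against healthy reference samples.
#'
#' @param bc a [BinCounts-class] on the panel's grid.
#' @param panel a [ReferencePanel-class].
#' @param chrom chromosome name.
#' @return a z-score.
#' @export
chromZFraction <- function(bc, panel, chrom) {
  cs <- panel@chromStats
  row <- cs[cs$chrom == chrom, ]
  if (nrow(row) != 1) stop("panel has no fraction statistics for ", chrom)
  if (is.na(row$sdFrac) || row$sdFrac <= 0)
    stop("panel fraction SD is zero for ", chrom)
  fr <- chromFractions(bc, denominator = "autosomal")
  (fr[[chrom]] - row$meanFrac) / row$sdFrac
}

#' Stouffer-aggregated chromosome z-score
#'
#' Combines the per-bin z-scores of a chromosome as
#' \eqn{Z = \sum_b z_b / \sqrt{n}} over its non-blacklisted bins: under the
#' null each bin is standard normal, so the aggregate is too, while a
#' consistent dosage shift grows as \eqn{\sqrt{n}}.
#'
#' @param profile a [SampleProfile-class].
#' @param chrom chromosome name.
#' @return a z-score.
#' @export
chromZStouffer <- function(profile, chrom) {
  onChrom <- as.character(seqnames(bins(binGrid(profile)))) == chrom
  z <- profile@z[onChrom]
  z <- z[!is.na(z)]
  if (length(z) == 0) stop("all bins blacklisted on ", chrom)
  sum(z) / sqrt(length(z))
}

#' Consensus autosomal aneuploidy calls
#'
#' Calls each autosome by two independent statistics — the bin-aggregated
#' Stouffer z ([chromZStouffer()]) and the whole-chromosome fraction z
#' ([chromZFraction()]) — and requires consensus: a trisomy is called only
#' when both z-scores are at or above \code{+zThreshold}, a monosomy only
#' when both are at or below \code{-zThreshold}. When exactly one method
#' crosses (or the two disagree in direction) the chromosome is flagged
#' \code{no_consensus} for manual review rather than silently resolved.
#' Autosomal monosomies are reported but annotated as rarely reportable.
#'
#' @param bc a [BinCounts-class].
#' @param profile the matching [SampleProfile-class].
#' @param panel the [ReferencePanel-class] both were computed against.
#' @param zThreshold z cutoff applied to both methods (default 3).
#' @return data.frame with columns \code{chrom}, \code{zStouffer},
#'   \code{zFraction}, \code{call} (normal / trisomy / monosomy /
#'   no_consensus) and \code{note}.
#' @export
callAutosomes <- function(bc, profile, panel, zThreshold = 3) {
  chroms <- seqlevels(bins(binGrid(panel)))
  chroms <- chroms[.isAutosome(chroms)]
  if (length(chroms) == 0) stop("no autosomes in grid")
  res <- lapply(chroms, function(ch) {
    zs <- chromZStouffer(profile, ch)
    zf <- chromZFraction(bc, panel, ch)
    upS <- zs >= zThreshold; upF <- zf >= zThreshold
    dnS <- zs <= -zThreshold; dnF <- zf <= -zThreshold
    call <- if (upS && upF) "trisomy"
            else if (dnS && dnF) "monosomy"
            else if (upS || upF || dnS || dnF) "no_consensus"
            else "normal"
    note <- if (call == "monosomy") "rarely reportable" else ""
    data.frame(chrom = ch, zStouffer = zs, zFraction = unname(zf),
               call = call, note = note)
  })
  out <- do.call(rbind, res)
  attr(out, "zThreshold") <- zThreshold
  out
}
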