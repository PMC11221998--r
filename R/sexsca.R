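#' Fetal sex by the chrY read-ratio statistic
#'
#' The ratio of high-quality mapped reads on chrY to all high-quality reads.
#' Female pregnancies cluster near zero (residual mismapping background);
#' male pregnancies rise with fetal fraction. The call is male when the
#' statistic is at or above the threshold (default 0.01, with ties going to
#' male since females sit below the threshold).
#'
#' @param bc a [BinCounts-class] whose grid includes chrY.
#' @param threshold decision threshold (default 0.01).
#' @return list with \code{method}, \code{statistic}, \code{threshold},
#'   \code{call} ("male"/"female").
#' @export
sexByChrYRatio <- function(bc, threshold = 0.01) {
  if (bc@totalHQReads <= 0) stop("zero total reads")
  ybins <- .chrYBins(binGrid(bc))
  if (!any(ybins)) stop("grid has no chrY bins")
  stat <- sum(readCounts(bc)[ybins]) / bc@totalHQReads
  list(method = "chry_ratio", statistic = stat, threshold = threshold,
       call = if (stat >= threshold) "male" else "female")
}

#' Fetal sex by the chrY marker-gene statistic
#'
#' The fraction of chrY-mapped reads that fall in the seven Y-specific
#' marker genes. In a male pregnancy chrY reads are genuinely Y-derived and
#' concentrate in Y-specific sequence; in a female pregnancy the few chrY
#' reads are mismaps scattered along the chromosome, so the gene fraction is
#' small. The call is male when the statistic reaches \code{threshold}
#' (default 0.5). With zero chrY reads the sample is called female with the
#' statistic reported as 0.
#'
#' @param x a [BinCounts-class] (gene counts taken at bin resolution) or a
#'   [RegionCounts-class] whose \code{denominator} is the all-chrY read
#'   count.
#' @param regions chrY marker genes ([chrYGeneRegions()] by default); must
#'   be non-empty.
#' @param exclude regions masked from counting ([parRegions()] by default).
#' @param threshold decision threshold (default 0.5).
#' @return list as in [sexByChrYRatio()], with \code{method = "chry_genes"}.
#' @export
sexByChrYGenes <- function(x, regions = chrYGeneRegions(),
                           exclude = parRegions(), threshold = 0.5) {
  if (is(x, "RegionCounts")) {
    geneReads <- regionUnionCount(x)
    yTotal <- x@denominator
  } else if (is(x, "BinCounts")) {
    if (length(regions(regions)) == 0) stop("empty gene region set")
    ybins <- .chrYBins(binGrid(x))
    yTotal <- sum(readCounts(x)[ybins])
    rc <- regionCountsFromBins(x, regions, exclude = exclude)
    geneReads <- regionUnionCount(rc)
  } else stop("x must be BinCounts or RegionCounts")
  if (yTotal <= 0)
    return(list(method = "chry_genes", statistic = 0,
                threshold = threshold, call = "female"))
  stat <- geneReads / yTotal
  list(method = "chry_genes", statistic = stat, threshold = threshold,
       call = if (stat >= threshold) "male" else "female")
}

#' Sex-chromosome aneuploidy call for a female-signature sample
#'
#' For samples classified female, the chrX dosage is tested by the
#' chromosome-fraction z-score against the (female-pregnancy) panel: XXX
#' when \eqn{z_X \ge} threshold, X0 (monosomy X) when \eqn{z_X \le -}
#' threshold, otherwise XX.
#'
#' @param bc a [BinCounts-class].
#' @param panel a [ReferencePanel-class].
#' @param zThreshold z cutoff (default 3).
#' @return list with \code{karyotype}, \code{zX}, \code{yLevel},
#'   \code{ffUsed}, \code{note}.
#' @export
scaFemale <- function(bc, panel, zThreshold = 3) {
  zx <- chromZFraction(bc, panel, .xName(binGrid(bc)))
  kar <- if (zx >= zThreshold) "XXX" else if (zx <= -zThreshold) "X0"
         else "XX"
  list(karyotype = kar, zX = unname(zx), yLevel = NA_real_,
       ffUsed = NA_real_, note = "")
}

.xName <- function(grid) {
  lv <- seqlevels(bins(grid))
  x <- lv[.isChrX(lv)]
  if (length(x) != 1) stop("grid lacks a chrX")
  x
}

#' Sex-chromosome aneuploidy call for a male-signature sample
#'
#' For samples classified male, two coordinates are examined: the chrX
#' fraction z-score against the female-pregnancy panel, and the y-level —
#' the fraction of reads in the seven chrY marker regions with the
#' pseudoautosomal regions excluded. Under a fetal karyotype with
#' \eqn{k_X} X and \eqn{k_Y} Y copies at fetal fraction \eqn{f}, the
#' expected chrX dosage factor is \eqn{1 + f (k_X - 2)/2} relative to the
#' panel mean, and the expected y-level is the female mismap background plus
#' \eqn{f \, k_Y \, c_{Y1}} with \eqn{c_{Y1}} the panel's per-Y-copy
#' calibration constant. The sample is assigned the karyotype (XY, XXY, XYY)
#' minimizing the squared standardized distance over the two coordinates;
#' when best and runner-up distances differ by less than 1 the call is
#' indeterminate. A male-signature sample whose y-level is indistinguishable
#' from the female background is flagged contradictory, not classified.
#'
#' @param bc a [BinCounts-class].
#' @param panel a [ReferencePanel-class] built with gene-region statistics.
#' @param ff fetal fraction (required; \code{NA} yields indeterminate).
#' @param regions,exclude chrY marker genes and masked regions.
#' @param zThreshold retained for interface symmetry (distances, not
#'   thresholds, drive the classification).
#' @return list as in [scaFemale()], with \code{distances} attached.
#' @export
scaMale <- function(bc, panel, ff, regions = chrYGeneRegions(),
                    exclude = parRegions(), zThreshold = 3) {
  if (is.na(ff))
    return(list(karyotype = "indeterminate", zX = NA_real_,
                yLevel = NA_real_, ffUsed = NA_real_,
                note = "fetal fraction unavailable"))
  if (ff <= 0) stop("ff must be > 0 for a male-signature sample")
  zx <- unname(chromZFraction(bc, panel, .xName(binGrid(bc))))
  rc <- regionCountsFromBins(bc, regions, exclude = exclude)
  total <- sum(readCounts(bc))
  y <- regionUnionCount(rc) / total
  bg <- if (is.na(panel@geneYMean)) 0 else panel@geneYMean
  bgSD <- if (is.na(panel@geneYSD) || panel@geneYSD <= 0) 1e-4
          else panel@geneYSD
  if (y < bg + 3 * bgSD)
    return(list(karyotype = "indeterminate", zX = zx, yLevel = y,
                ffUsed = ff, note = "contradictory: male call with female-level chrY signal"))
  cs <- panel@chromStats
  xrow <- cs[cs$chrom == .xName(binGrid(bc)), ]
  karyos <- list(XY = c(1, 1), XXY = c(2, 1), XYY = c(1, 2))
  sdY <- sqrt(bgSD^2 + y / total)
  d <- vapply(karyos, function(k) {
    zxExp <- xrow$meanFrac * ff * (k[1] - 2) / 2 / xrow$sdFrac
    yExp <- bg + ff * k[2] * panel@cY1
    (zx - zxExp)^2 + ((y - yExp) / sdY)^2
  }, 0)
  ord <- order(d)
  kar <- names(d)[ord[1]]
  note <- ""
  if (d[ord[2]] - d[ord[1]] < 1) {
    kar <- "indeterminate"
    note <- sprintf("ambiguous: %s vs %s", names(d)[ord[1]], names(d)[ord[2]])
  }
  out <- list(karyotype = kar, zX = zx, yLevel = y, ffUsed = ff, note = note)
  attr(out, "distances") <- d
  out
}
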