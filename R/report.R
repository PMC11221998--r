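#' Diagnostic confusion metrics
#'
#' Positive/negative predictive value, sensitivity and specificity (in
#' percent) from a condition's confusion counts. A metric whose denominator
#' is zero is undefined and returned as \code{NA}.
#'
#' @param tp,fp,fn,tn true/false positive and negative counts (>= 0).
#' @return named numeric vector \code{ppv}, \code{npv}, \code{sensitivity},
#'   \code{specificity}, in percent.
#' @examples
#' confusionMetrics(tp = 7, fp = 1, fn = 0, tn = 0)[["ppv"]]  # 87.5
#' @export
confusionMetrics <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  c(ppv = pct(tp, tp + fp), npv = pct(tn, tn + fn),
    sensitivity = pct(tp, tp + fn), specificity = pct(tn, tn + fp))
}

#' Export circos-style genome tracks
#'
#' Writes the per-bin z-scores (inner-ring track) and log2 ratios
#' (outer-ring track) of a profile as circos-compatible text files
#' (\code{chrom start end value}, 0-based half-open, grid order;
#' blacklisted bins omitted). Re-exporting the same profile is
#' byte-identical.
#'
#' @param profile a [SampleProfile-class].
#' @param dir output directory.
#' @param prefix file-name prefix (default: the sample ID).
#' @return character vector of the two file paths (z, log2).
#' @export
circosExport <- function(profile, dir, prefix = sampleID(profile)) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  b <- bins(binGrid(profile))
  writeTrack <- function(values, path) {
    ok <- !is.na(values)
    lines <- sprintf("%s %d %d %s", as.character(seqnames(b))[ok],
                     start(b)[ok] - 1L, end(b)[ok],
                     formatC(values[ok], format = "g", digits = 8))
    writeLines(lines, path)
    path
  }
  zPath <- file.path(dir, paste0(prefix, "_z.txt"))
  lPath <- file.path(dir, paste0(prefix, "_log2.txt"))
  c(writeTrack(profile@z, zPath), writeTrack(profile@log2Ratio, lPath))
}

#' Run the full NIPT analysis on one sample
#'
#' Orchestrates the pipeline: sex determination (both chrY methods), fetal
#' fraction (chrY scaling for male pregnancies, the regression model when
#' supplied for female ones, or an explicit \code{ff}), the sample QC gate,
#' panel profiling, consensus autosomal aneuploidy calls, sex-chromosome
#' aneuploidy classification, and CNV segmentation. A sample failing the QC
#' gate still yields a report, with calls suppressed and the violated
#' criteria listed.
#'
#' @param bc a [BinCounts-class] on the panel's grid.
#' @param panel a [ReferencePanel-class].
#' @param ff optional externally known fetal fraction (overrides
#'   estimation).
#' @param ffModel optional [FFRegressionModel-class] for female pregnancies.
#' @param zThreshold z cutoff for aneuploidy and SCA calls (default 3).
#' @param splitZ CNV segmentation split threshold (default 5).
#' @param minReads,minFF QC gate thresholds (see [applySampleGate()]).
#' @param regions,exclude chrY marker genes and PAR mask (defaults shipped
#'   with the package); used when the grid has a chrY.
#' @return a \code{KaryotypeReport}: a list with elements \code{sampleID},
#'   \code{qc}, \code{sex}, \code{ff}, \code{autosomes}, \code{sca},
#'   \code{cnv}, \code{fingerprint}.
#' @export
runPipeline <- function(bc, panel, ff = NULL, ffModel = NULL,
                        zThreshold = 3, splitZ = 5, minReads = 1.5e6,
                        minFF = 0.04, regions = NULL, exclude = NULL) {
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  grid <- binGrid(bc)
  hasY <- any(.chrYBins(grid))
  if (hasY && is.null(regions))
    regions <- tryCatch(chrYGeneRegions(), error = function(e) NULL)
  if (hasY && is.null(exclude))
    exclude <- tryCatch(parRegions(), error = function(e) NULL)

  sex <- stage("sex", {
    s1 <- if (hasY) sexByChrYRatio(bc) else
      list(method = "chry_ratio", statistic = NA_real_, threshold = 0.01,
           call = "indeterminate")
    s2 <- if (hasY && !is.null(regions))
      sexByChrYGenes(bc, regions = regions, exclude = exclude) else
      list(method = "chry_genes", statistic = NA_real_, threshold = 0.5,
           call = "indeterminate")
    list(chryRatio = s1, chryGenes = s2, call = s1$call)
  })

  ffEst <- stage("ff", {
    est <- list()
    if (sex$call == "male" && !is.na(panel@yMean))
      est$ffy <- ffYFromPanel(bc, panel)
    if (!is.null(ffModel))
      est$regression <- applyFFRegression(ffModel, bc)
    used <- if (!is.null(ff)) ff
      else if (sex$call == "male" && !is.null(est$ffy)) est$ffy$value
      else if (!is.null(est$regression)) est$regression$value
      else NA_real_
    est$used <- used
    est
  })

  qc <- stage("qc", applySampleGate(bc@totalHQReads, ffEst$used,
                                    minReads = minReads, minFF = minFF))
  fingerprint <- list(package = "shallowNIPT",
                      version = as.character(utils::packageVersion("shallowNIPT")),
                      zThreshold = zThreshold, splitZ = splitZ,
                      minReads = minReads, minFF = minFF,
                      binSize = binSize(grid))
  report <- list(sampleID = sampleID(bc), qc = qc, sex = sex, ff = ffEst,
                 autosomes = NULL, sca = NULL, cnv = NULL,
                 fingerprint = fingerprint)
  class(report) <- "KaryotypeReport"
  if (!qc$pass) return(report)

  profile <- stage("profile", profileSample(bc, panel))
  report$autosomes <- stage("aneuploidy",
    callAutosomes(bc, profile, panel, zThreshold = zThreshold))
  report$sca <- stage("sca", {
    if (!any(.chrXBins(grid))) NULL
    else if (sex$call == "male")
      scaMale(bc, panel, ff = ffEst$used, regions = regions,
              exclude = exclude, zThreshold = zThreshold)
    else scaFemale(bc, panel, zThreshold = zThreshold)
  })
  report$cnv <- stage("cnv", {
    chroms <- seqlevels(bins(grid))
    # sub-chromosomal events only: a chromosome yielding a single segment
    # has no internal boundary, and its dosage is the aneuploidy callers'
    # domain, not a CNV
    segs <- do.call(rbind, lapply(chroms[.isAutosome(chroms)], function(ch) {
      s <- segmentBins(profile, ch, splitZ = splitZ)
      if (nrow(s) > 1) s else s[0, ]
    }))
    if (is.na(ffEst$used) || ffEst$used <= 0) NULL
    else callSegments(segs, ff = ffEst$used, zThreshold = zThreshold)
  })
  report
}

#' @export
print.KaryotypeReport <- function(x, ...) {
  cat(sprintf("KaryotypeReport for '%s'\n", x$sampleID))
  cat(sprintf("  QC: %s%s\n", if (x$qc$pass) "pass" else "FAIL",
              if (length(x$qc$reasons))
                paste0(" (", paste(x$qc$reasons, collapse = ", "), ")")
              else ""))
  cat(sprintf("  sex: %s (chrY ratio %.4f); ff: %s\n", x$sex$call,
              x$sex$chryRatio$statistic,
              ifelse(is.na(x$ff$used), "NA", sprintf("%.3f", x$ff$used))))
  if (!is.null(x$autosomes)) {
    ab <- x$autosomes[x$autosomes$call != "normal", ]
    cat(sprintf("  autosomes: %s\n", if (nrow(ab) == 0) "all normal"
                else paste(ab$chrom, ab$call, collapse = "; ")))
  }
  if (!is.null(x$sca)) cat(sprintf("  sex karyotype: %s\n", x$sca$karyotype))
  if (!is.null(x$cnv) && nrow(x$cnv) > 0)
    cat(sprintf("  CNV: %s\n", paste(sprintf("%s %s %.1f Mb", x$cnv$chrom,
                x$cnv$type, x$cnv$sizeMb), collapse = "; ")))
  invisible(x)
}

#' Write / read a KaryotypeReport as JSON
#'
#' The JSON serialization is lossless for all calls and settings, so a
#' report plus its config fingerprint reproduces the run.
#'
#' @param report a \code{KaryotypeReport} from [runPipeline()].
#' @param path JSON file path.
#' @return \code{readKaryotypeReport} returns the report list.
#' @export
writeKaryotypeReport <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null",
                       dataframe = "rows")
  invisible(path)
}

#' @rdname writeKaryotypeReport
#' @export
readKaryotypeReport <- function(path) {
  rep <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  class(rep) <- "KaryotypeReport"
  rep
}
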