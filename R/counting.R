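#' @importFrom Rsamtools ScanBamParam scanBamFlag scanBam BamFile
#' @importFrom GenomicRanges findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

# Map BAM reference names onto grid chromosome names ("chr" prefix tolerant).
.matchChrom <- function(bamChroms, gridChroms) {
  out <- stats::setNames(rep(NA_character_, length(bamChroms)), bamChroms)
  for (bc in bamChroms) {
    cand <- c(bc, paste0("chr", bc), sub("^chr", "", bc))
    hit <- cand[cand %in% gridChroms]
    if (length(hit)) out[[bc]] <- hit[1]
  }
  out
}

.scanPrimary <- function(bam, mapqMin) {
  param <- ScanBamParam(
    what = c("rname", "pos", "strand", "mapq"),
    flag = scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
                       isSupplementaryAlignment = FALSE))
  r <- scanBam(bam, param = param)[[1]]
  ok <- !is.na(r$mapq) & r$mapq >= mapqMin & !is.na(r$pos)
  list(rname = as.character(r$rname)[ok], pos = r$pos[ok],
       strand = as.character(r$strand)[ok])
}

#' Count aligned reads into bins
#'
#' Each primary, mapped, MAPQ-passing read is assigned to exactly the bin
#' containing its leftmost aligned position (reads spanning a bin boundary are
#' not split). Secondary, supplementary and unmapped records are excluded;
#' with \code{dedupPositions}, only the first read at each
#' (chromosome, position, strand) is kept. \code{totalHQReads} counts all
#' surviving high-quality reads genome-wide, including contigs absent from
#' the grid.
#'
#' @param bam path to a BAM file (or \code{Rsamtools::BamFile}).
#' @param grid a [BinGrid-class]; chromosome names are matched against the
#'   BAM header with "chr"-prefix normalization.
#' @param mapqMin MAPQ cutoff defining "high-quality" (default 30).
#' @param dedupPositions collapse position-level duplicates (default FALSE).
#' @param sampleID sample identifier (default: BAM basename).
#' @return a [BinCounts-class].
#' @export
binCountsFromBam <- function(bam, grid, mapqMin = 30, dedupPositions = FALSE,
                             sampleID = NULL) {
  stopifnot(is(grid, "BinGrid"))
  if (is.null(sampleID))
    sampleID <- sub("\\.bam$", "", basename(if (is(bam, "BamFile"))
      Rsamtools::path(bam) else bam))
  r <- .scanPrimary(bam, mapqMin)
  if (dedupPositions) {
    keep <- !duplicated(paste(r$rname, r$pos, r$strand))
    r <- lapply(r, `[`, keep)
  }
  gridChroms <- seqlevels(bins(grid))
  if (length(r$pos)) {
    map <- .matchChrom(unique(r$rname), gridChroms)
    if (all(is.na(map)))
      stop("no overlapping chromosome names between BAM header and grid")
  }
  counts <- numeric(length(bins(grid)))
  b <- bins(grid)
  offs <- c(0, cumsum(table(factor(as.character(seqnames(b)),
                                   levels = gridChroms))))
  names(offs) <- c(gridChroms, "_end")
  w <- binSize(grid)
  if (length(r$pos)) {
    chrom <- unname(map[r$rname])
    inGrid <- !is.na(chrom)
    chrom <- chrom[inGrid]; pos <- r$pos[inGrid]
    len <- seqlengths(seqinfo(b))[chrom]
    okPos <- pos >= 1 & pos <= len
    chrom <- chrom[okPos]; pos <- pos[okPos]
    idx <- offs[chrom] + (pos - 1) %/% w + 1
    tab <- tabulate(idx, nbins = length(counts))
    counts <- as.numeric(tab)
  }
  new("BinCounts", sampleID = sampleID, grid = grid, counts = counts,
      totalHQReads = length(r$pos), mapqMin = as.numeric(mapqMin),
      dedupPositions = dedupPositions)
}

#' Per-chromosome read fractions
#'
#' Fraction of binned reads per chromosome. With
#' \code{denominator = "binned"} (the default) fractions are taken over all
#' binned reads and sum to 1 over the grid's chromosomes. With
#' \code{denominator = "autosomal"} each chromosome's reads are divided by
#' the autosomal binned total; this is the denominator used by the panel and
#' the z-statistics, so that the (fetal-sex-dependent) sex-chromosome signal
#' cannot leak into autosomal dosage statistics.
#'
#' @param bc a [BinCounts-class].
#' @param denominator \code{"binned"} or \code{"autosomal"}.
#' @return named numeric vector of fractions, one per chromosome.
#' @export
chromFractions <- function(bc, denominator = c("binned", "autosomal")) {
  denominator <- match.arg(denominator)
  chrom <- as.character(seqnames(bins(binGrid(bc))))
  tot <- sum(readCounts(bc))
  if (tot <= 0) stop("zero binned reads")
  perChrom <- tapply(readCounts(bc), factor(chrom, levels = unique(chrom)),
                     sum)
  den <- if (denominator == "binned") tot else
    sum(perChrom[.isAutosome(names(perChrom))])
  if (den <= 0) stop("zero reads in denominator")
  out <- as.numeric(perChrom) / den
  names(out) <- names(perChrom)
  out
}

#' Count reads whose leftmost position falls in labelled regions
#'
#' Per-label counts of high-quality reads whose leftmost aligned position
#' lies inside the region and not inside any \code{exclude} region (e.g. the
#' pseudoautosomal regions). A read inside two overlapping labelled regions
#' is counted once under each containing label; \code{unionCount} counts each
#' read once.
#'
#' @param bam path to a BAM file.
#' @param regions a [RegionSet-class]; must be non-empty.
#' @param mapqMin MAPQ cutoff (default 30).
#' @param exclude optional [RegionSet-class] of masked regions.
#' @param dedupPositions collapse position-level duplicates.
#' @param sampleID sample identifier.
#' @return a [RegionCounts-class]; \code{denominator} is filled with the
#'   total high-quality read count and can be reset by the caller for other
#'   statistic contexts. The union count over all labels is available as
#'   \code{attr(counts, "unionCount")} via [regionUnionCount()].
#' @export
regionCountsFromBam <- function(bam, regions, mapqMin = 30, exclude = NULL,
                                dedupPositions = FALSE, sampleID = "sample") {
  stopifnot(is(regions, "RegionSet"))
  if (length(regions(regions)) == 0) stop("empty region set")
  r <- .scanPrimary(bam, mapqMin)
  if (dedupPositions) {
    keep <- !duplicated(paste(r$rname, r$pos, r$strand))
    r <- lapply(r, `[`, keep)
  }
  rr <- regions(regions)
  map <- .matchChrom(unique(r$rname), unique(as.character(seqnames(rr))))
  chrom <- unname(map[r$rname])
  pos <- GRanges(ifelse(is.na(chrom), "*unmatched*", chrom),
                 IRanges(r$pos, width = 1))
  inExclude <- rep(FALSE, length(pos))
  if (!is.null(exclude) && length(regions(exclude)) > 0) {
    ex <- regions(exclude)
    inExclude <- IRanges::overlapsAny(pos, ex)
  }
  hits <- findOverlaps(pos, rr)
  okHit <- !inExclude[queryHits(hits)]
  lab <- mcols(rr)$label
  cnt <- stats::setNames(numeric(length(rr)), lab)
  tt <- table(factor(lab[subjectHits(hits)[okHit]], levels = lab))
  cnt[names(tt)] <- as.numeric(tt)
  attr(cnt, "unionCount") <- length(unique(queryHits(hits)[okHit]))
  new("RegionCounts", sampleID = sampleID, setName = regions@name,
      counts = cnt, denominator = length(r$pos))
}

#' Bin-resolution region counts from BinCounts
#'
#' Approximates region-level counts from binned counts: each label receives
#' the summed counts of the bins overlapping its region(s), skipping bins
#' that overlap any \code{exclude} region. This is the region statistic
#' available when only bin counts exist (e.g. simulated cohorts); its
#' resolution is the bin size.
#'
#' @param bc a [BinCounts-class].
#' @param regions a [RegionSet-class]; must be non-empty.
#' @param exclude optional [RegionSet-class].
#' @return a [RegionCounts-class] (denominator = total binned reads), with
#'   the union count of all region-overlapping bins in
#'   \code{attr(counts, "unionCount")}.
#' @export
regionCountsFromBins <- function(bc, regions, exclude = NULL) {
  stopifnot(is(regions, "RegionSet"))
  if (length(regions(regions)) == 0) stop("empty region set")
  b <- bins(binGrid(bc))
  rr <- regions(regions)
  excluded <- rep(FALSE, length(b))
  if (!is.null(exclude) && length(regions(exclude)) > 0)
    excluded <- IRanges::overlapsAny(b, regions(exclude))
  hits <- findOverlaps(b, rr)
  ok <- !excluded[queryHits(hits)]
  lab <- mcols(rr)$label
  cnt <- stats::setNames(numeric(length(rr)), lab)
  for (j in seq_along(rr)) {
    bi <- queryHits(hits)[ok & subjectHits(hits) == j]
    cnt[j] <- sum(readCounts(bc)[bi])
  }
  ubins <- unique(queryHits(hits)[ok])
  attr(cnt, "unionCount") <- sum(readCounts(bc)[ubins])
  new("RegionCounts", sampleID = sampleID(bc), setName = regions@name,
      counts = cnt, denominator = sum(readCounts(bc)))
}

#' Union read count of a RegionCounts object
#'
#' Reads falling in the union of all labelled regions, counted once each.
#' @param rc a [RegionCounts-class].
#' @return a count.
#' @export
regionUnionCount <- function(rc) {
  u <- attr(rc@counts, "unionCount")
  if (is.null(u)) sum(rc@counts) else u
}

#' Serialize / read BinCounts as TSV
#'
#' A JSON header line (prefixed \code{#}) records the sample metadata;
#' the table has columns \code{chrom, start, end, count} (0-based half-open)
#' in grid order.
#'
#' @param bc a [BinCounts-class].
#' @param grid the [BinGrid-class] the file was written against.
#' @param path file path.
#' @return \code{readBinCounts} returns a [BinCounts-class].
#' @export
writeBinCounts <- function(bc, path) {
  b <- bins(binGrid(bc))
  hdr <- paste0("#", jsonlite::toJSON(list(
    sample_id = sampleID(bc), total_hq_reads = bc@totalHQReads,
    mapq_min = bc@mapqMin, dedup_positions = bc@dedupPositions),
    auto_unbox = TRUE, digits = NA))
  df <- data.frame(chrom = as.character(seqnames(b)), start = start(b) - 1L,
                   end = end(b), count = readCounts(bc))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBinCounts
#' @export
readBinCounts <- function(path, grid) {
  hdr <- readLines(path, n = 1)
  meta <- jsonlite::fromJSON(sub("^#", "", hdr))
  df <- utils::read.delim(path, skip = 1)
  if (nrow(df) != length(bins(grid))) stop("bin count rows do not match grid")
  new("BinCounts", sampleID = meta$sample_id, grid = grid,
      counts = as.numeric(df$count), totalHQReads = meta$total_hq_reads,
      mapqMin = meta$mapq_min, dedupPositions = meta$dedup_positions)
}
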