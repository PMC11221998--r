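#' @importFrom Rsamtools FaFile scanFa indexFa
#' @importFrom Biostrings letterFrequency readDNAStringSet getSeq width
NULL

# GRCh37 chromosome lengths (chr1..22, X, Y), primary assembly.
.GRCH37_LEN <- c(
  chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
  chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
  chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
  chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
  chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
  chr21 = 48129895, chr22 = 51304566, chrX = 155270560, chrY = 59373566)

#' Declare a genome build
#'
#' A genome build is a named, ordered set of chromosomes with lengths,
#' represented as a \code{Seqinfo}. The chromosome order is stable and is
#' inherited by every grid, count set and profile downstream.
#'
#' @param name build name, e.g. \code{"GRCh37"}.
#' @param chromosomes named numeric vector of chromosome lengths in bp.
#' @return a \code{Seqinfo}.
#' @examples
#' genomeBuild("toy", c(chrA = 2.5e6, chrB = 1e6))
#' @export
genomeBuild <- function(name, chromosomes) {
  if (length(chromosomes) == 0) stop("empty genome build")
  if (is.null(names(chromosomes)) || anyDuplicated(names(chromosomes)))
    stop("chromosome names must be present and unique")
  if (any(chromosomes <= 0)) stop("chromosome lengths must be > 0")
  Seqinfo(seqnames = names(chromosomes),
          seqlengths = as.integer(chromosomes), genome = name)
}

#' The GRCh37 build (chr1-22, X, Y)
#'
#' Primary-assembly chromosome lengths of GRCh37/hg19, the build the package
#' defaults assume (PAR coordinates, chrY gene set).
#'
#' @return a \code{Seqinfo} for chr1..chr22, chrX, chrY.
#' @export
grch37 <- function() genomeBuild("GRCh37", .GRCH37_LEN)

#' Tile a genome build into fixed-width bins
#'
#' Per chromosome, \code{ceiling(length / binSize)} bins; the last bin may be
#' shorter. GC content starts unannotated (\code{NA}) and all bins start
#' usable. The default 1 Mb resolution serves whole-chromosome aneuploidy
#' analysis; copy-number-variant mode typically uses 100 kb.
#'
#' @param build a \code{Seqinfo} from [genomeBuild()] or [grch37()].
#' @param binSize bin width in bp (> 0).
#' @return a [BinGrid-class].
#' @examples
#' grid <- makeBins(grch37(), 1e6)
#' sum(as.character(GenomicRanges::seqnames(bins(grid))) == "chr21")  # 49
#' @export
makeBins <- function(build, binSize = 1e6) {
  if (!is(build, "Seqinfo")) stop("build must be a Seqinfo (see genomeBuild)")
  if (length(seqlevels(build)) == 0) stop("empty genome build")
  binSize <- as.integer(binSize)
  if (is.na(binSize) || binSize <= 0L) stop("binSize must be > 0")
  pieces <- lapply(seqlevels(build), function(chr) {
    len <- seqlengths(build)[[chr]]
    s <- seq.int(1L, len, by = binSize)
    GRanges(chr, IRanges(s, end = pmin(s + binSize - 1L, len)),
            seqinfo = build)
  })
  gr <- suppressWarnings(do.call(c, pieces))
  mcols(gr)$gc <- NA_real_
  mcols(gr)$usable <- TRUE
  new("BinGrid", bins = gr, binSize = binSize)
}

.gcOf <- function(seqs) {
  acgt <- letterFrequency(seqs, c("A", "C", "G", "T"))
  info <- rowSums(acgt)
  gc <- ifelse(info > 0, (acgt[, "C"] + acgt[, "G"]) / info, NA_real_)
  nfrac <- 1 - info / pmax(Biostrings::width(seqs), 1L)
  list(gc = as.numeric(gc), nfrac = as.numeric(nfrac))
}

#' Annotate per-bin GC content from a genome FASTA
#'
#' GC is computed as (G+C)/(A+C+G+T) per bin, ignoring ambiguous bases; bins
#' with more than 50\% N are flagged unusable. GC is strand-symmetric.
#'
#' @param grid a [BinGrid-class].
#' @param genome a FASTA path, an \code{Rsamtools::FaFile}, or a named
#'   \code{DNAStringSet} covering every chromosome of the grid.
#' @param maxNFrac N fraction above which a bin is flagged unusable.
#' @return the grid with \code{gc} and \code{usable} filled in.
#' @export
annotateGC <- function(grid, genome, maxNFrac = 0.5) {
  stopifnot(is(grid, "BinGrid"))
  b <- bins(grid)
  if (is(genome, "DNAStringSet")) {
    missing <- setdiff(seqlevels(b), names(genome))
    if (length(missing))
      stop("chromosome(s) absent from sequence source: ",
           paste(missing, collapse = ", "))
    seqs <- Biostrings::DNAStringSet(lapply(seq_along(b), function(i) {
      Biostrings::subseq(genome[[as.character(seqnames(b)[i])]],
                         start(b)[i], end(b)[i])
    }))
  } else {
    fa <- if (is(genome, "FaFile")) genome else {
      if (!file.exists(paste0(path.expand(as.character(genome)), ".fai")))
        indexFa(genome)
      FaFile(genome)
    }
    fachr <- GenomeInfoDb::seqnames(seqinfo(fa))
    missing <- setdiff(seqlevels(b), fachr)
    if (length(missing))
      stop("chromosome(s) absent from sequence source: ",
           paste(missing, collapse = ", "))
    seqs <- scanFa(fa, GRanges(seqnames(b), IRanges(start(b), end(b))))
  }
  res <- .gcOf(seqs)
  mcols(b)$gc <- res$gc
  mcols(b)$usable <- mcols(b)$usable & (res$nfrac <= maxNFrac)
  new("BinGrid", bins = b, binSize = binSize(grid))
}

#' Load a labelled region set from a BED file
#'
#' BED records are 0-based half-open; column 4, when present, provides the
#' region labels (otherwise regions are auto-numbered). Records with
#' \code{start >= end} are rejected.
#'
#' @param path BED file path (3 or more columns, tab-separated).
#' @param name name for the set.
#' @return a [RegionSet-class]. An empty file yields an empty set; operations
#'   that require a non-empty set check for that explicitly.
#' @export
loadRegions <- function(path, name) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0)
    return(new("RegionSet", name = name,
               regions = GRanges(label = character(0))))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3)) stop("malformed BED record (fewer than 3 columns)")
  chrom <- vapply(fields, `[[`, "", 1L)
  s0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  e0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (any(is.na(s0)) || any(is.na(e0)) || any(s0 < 0))
    stop("malformed BED coordinates")
  if (any(s0 >= e0))
    stop("BED record with start >= end at line ", which(s0 >= e0)[1])
  label <- ifelse(ncols >= 4, vapply(fields, function(f)
    if (length(f) >= 4) f[[4]] else "", ""), "")
  label[!nzchar(label)] <- paste0("region_", which(!nzchar(label)))
  gr <- GRanges(chrom, IRanges(s0 + 1, e0), label = label)
  new("RegionSet", name = name, regions = gr)
}

#' Default chrY marker genes and pseudoautosomal regions (GRCh37)
#'
#' \code{chrYGeneRegions()} returns the seven Y-specific single-copy genes the
#' chrY-gene sex statistic counts over (SRY, RPS4Y1, ZFY, USP9Y, DDX3Y, UTY,
#' EIF1AY); \code{parRegions()} returns PAR1/PAR2 on both sex chromosomes.
#' Both are read from editable BED files shipped with the package and can be
#' replaced with [loadRegions()].
#'
#' @return a [RegionSet-class].
#' @export
chrYGeneRegions <- function() {
  loadRegions(system.file("extdata", "chrY_genes.grch37.bed",
                          package = "shallowNIPT", mustWork = TRUE),
              "chrY_genes")
}

#' @rdname chrYGeneRegions
#' @export
parRegions <- function() {
  loadRegions(system.file("extdata", "par.grch37.bed",
                          package = "shallowNIPT", mustWork = TRUE),
              "PAR")
}

#' Serialize / read a BinGrid as TSV
#'
#' Columns \code{chrom, start, end, gc, usable}, 0-based half-open, one row
#' per bin in grid order. A header line \code{# build=<name> bin_size=<bp>}
#' precedes the table. Serialization is deterministic: the same build and bin
#' size yield byte-identical files.
#'
#' @param grid a [BinGrid-class].
#' @param path output/input TSV path.
#' @return \code{readBinGrid} returns a [BinGrid-class].
#' @export
writeBinGrid <- function(grid, path) {
  b <- bins(grid)
  hdr <- sprintf("# build=%s bin_size=%d",
                 GenomeInfoDb::genome(seqinfo(b))[1], binSize(grid))
  df <- data.frame(chrom = as.character(seqnames(b)), start = start(b) - 1L,
                   end = end(b), gc = mcols(b)$gc, usable = mcols(b)$usable)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBinGrid
#' @export
readBinGrid <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec("build=(\\S+) bin_size=(\\d+)", hdr))[[1]]
  if (length(m) != 3) stop("missing BinGrid header line")
  df <- utils::read.delim(path, skip = 1)
  lens <- tapply(df$end, factor(df$chrom, levels = unique(df$chrom)), max)
  build <- genomeBuild(m[2], stats::setNames(as.numeric(lens), names(lens)))
  grid <- makeBins(build, as.integer(m[3]))
  b <- bins(grid)
  mcols(b)$gc <- df$gc
  mcols(b)$usable <- df$usable
  new("BinGrid", bins = b, binSize = binSize(grid))
}

# chromosome classification helpers -------------------------------------------

.isAutosome <- function(chrom) grepl("^(chr)?[0-9]+$", chrom)
.isChrX <- function(chrom) grepl("^(chr)?X$", chrom)
.isChrY <- function(chrom) grepl("^(chr)?Y$", chrom)

.autosomeBins <- function(grid) .isAutosome(as.character(seqnames(bins(grid))))
.chrYBins <- function(grid) .isChrY(as.character(seqnames(bins(grid))))
.chrXBins <- function(grid) .isChrX(as.character(seqnames(bins(grid))))
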