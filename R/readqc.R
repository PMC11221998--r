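#' Filter raw reads by length, mean quality and duplication
#'
#' Re-implements the read-level exclusion contract applied upstream of
#' alignment: reads shorter than \code{minLength} bp or with mean per-base
#' Phred quality below \code{minMeanQ} are dropped, and (optionally) exact
#' duplicate sequences are collapsed to their first occurrence. Reads are kept
#' or dropped whole; no trimming is performed. Surviving reads keep their
#' input order.
#'
#' Input must be 4-line FASTQ (optionally gzipped). Phred encoding is
#' Sanger/+33 by default.
#'
#' @param input path to a FASTQ file.
#' @param output optional path for the filtered FASTQ; omitted = no file
#'   written (statistics only).
#' @param minLength minimum read length in bp (default 35).
#' @param minMeanQ minimum mean Phred score (default 20).
#' @param dedup collapse exact duplicate sequences (default TRUE).
#' @param phredOffset quality encoding offset (default 33).
#' @return a list with elements \code{stats} (counts: \code{readsIn},
#'   \code{removedShort}, \code{removedLowQ}, \code{duplicatesRemoved},
#'   \code{readsOut}; they always reconcile as
#'   readsOut = readsIn - removedShort - removedLowQ - duplicatesRemoved)
#'   and \code{keep} (logical vector over input records).
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' simulateFastq(fq, nReads = 100, length = 50, seed = 1)
#' filterReads(fq)$stats
#' @export
filterReads <- function(input, output = NULL, minLength = 35, minMeanQ = 20,
                        dedup = TRUE, phredOffset = 33) {
  stopifnot(minLength >= 1, minMeanQ >= 0)
  lines <- readLines(input)
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ: ", length(lines), " lines (not a multiple of 4)")
  n <- length(lines) %/% 4
  if (n == 0) {
    stats <- list(readsIn = 0L, removedShort = 0L, removedLowQ = 0L,
                  duplicatesRemoved = 0L, readsOut = 0L)
    if (!is.null(output)) writeLines(character(0), output)
    return(list(stats = stats, keep = logical(0)))
  }
  hd <- lines[seq(1, by = 4, length.out = n)]
  sq <- lines[seq(2, by = 4, length.out = n)]
  pl <- lines[seq(3, by = 4, length.out = n)]
  qu <- lines[seq(4, by = 4, length.out = n)]
  bad <- which(!startsWith(hd, "@") | !startsWith(pl, "+") |
                 nchar(sq) != nchar(qu))
  if (length(bad))
    stop("malformed FASTQ record at index ", bad[1])

  len <- nchar(sq)
  meanq <- vapply(qu, function(q) {
    mean(as.integer(charToRaw(q))) - phredOffset
  }, 0, USE.NAMES = FALSE)

  short <- len < minLength
  lowq <- !short & meanq < minMeanQ
  keep <- !short & !lowq
  dupRemoved <- 0L
  if (dedup) {
    dup <- keep & duplicated(ifelse(keep, sq, NA_character_),
                             incomparables = NA)
    dupRemoved <- sum(dup)
    keep <- keep & !dup
  }
  stats <- list(readsIn = n, removedShort = sum(short),
                removedLowQ = sum(lowq), duplicatesRemoved = dupRemoved,
                readsOut = sum(keep))
  if (!is.null(output)) {
    idx <- which(keep)
    out <- character(4L * length(idx))
    out[seq(1, by = 4, length.out = length(idx))] <- hd[idx]
    out[seq(2, by = 4, length.out = length(idx))] <- sq[idx]
    out[seq(3, by = 4, length.out = length(idx))] <- pl[idx]
    out[seq(4, by = 4, length.out = length(idx))] <- qu[idx]
    con <- if (grepl("\\.gz$", output)) gzfile(output, "w")
           else file(output, "w")
    writeLines(out, con)
    close(con)
  }
  list(stats = stats, keep = keep)
}

#' Sample-level QC gate
#'
#' A sample is analyzable when it has at least \code{minReads} high-quality
#' reads and a fetal fraction of at least \code{minFF} (default 1.5 million
#' reads and 4\%, the thresholds below which NIPT sensitivity degrades).
#' A missing fetal fraction fails the fetal-fraction criterion explicitly.
#'
#' @param totalHQReads high-quality read count of the sample.
#' @param ff fetal fraction in [0,1], or \code{NA} when unavailable.
#' @param minReads read-count threshold (default 1,500,000).
#' @param minFF fetal-fraction threshold (default 0.04).
#' @return list with \code{pass} (logical) and \code{reasons} (character
#'   vector naming each violated criterion; empty on pass).
#' @examples
#' applySampleGate(2e6, 0.08)           # pass
#' applySampleGate(1.4e6, 0.10)$reasons # "reads"
#' @export
applySampleGate <- function(totalHQReads, ff, minReads = 1.5e6,
                            minFF = 0.04) {
  stopifnot(minReads >= 0, minFF >= 0)
  if (is.na(totalHQReads) || totalHQReads < 0)
    stop("negative or missing read count")
  reasons <- character(0)
  if (totalHQReads < minReads) reasons <- c(reasons, "reads")
  if (is.na(ff)) {
    reasons <- c(reasons, "ff_missing")
  } else {
    if (ff < 0 || ff > 1) stop("ff must be in [0,1] or NA")
    if (ff < minFF) reasons <- c(reasons, "ff")
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}
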