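# Synthetic cfDNA cohort simulator. The generative model is the same dosage
# model the callers assume: per-bin expected counts proportional to
# baseline weight x dosage (1 + f*(k-2)/2) x GC bias x fetal signature,
# chrY modelled as mismapping background + f * kY * cY1, counts drawn
# negative-binomially with variance (1 + dispersion) * mean.

.karyotypeInfo <- function(label) {
  tri <- NA_character_
  if (label %in% c("euploid", "euploid-female")) {
    kX <- 2; kY <- 0
  } else if (label == "euploid-male") {
    kX <- 1; kY <- 1
  } else if (grepl("^T[0-9]+(-male)?$", label)) {
    male <- grepl("-male$", label)
    kX <- if (male) 1 else 2
    kY <- if (male) 1 else 0
    tri <- paste0("chr", sub("^T([0-9]+).*$", "\\1", label))
  } else if (label == "X0") {
    kX <- 1; kY <- 0
  } else if (label == "XXX") {
    kX <- 3; kY <- 0
  } else if (label == "XXY") {
    kX <- 2; kY <- 1
  } else if (label == "XYY") {
    kX <- 1; kY <- 2
  } else stop("unknown karyotype label: ", label)
  list(kX = kX, kY = kY, trisomy = tri,
       sex = if (kY >= 1) "male" else "female")
}

# Deterministic per-grid pseudo-noise (irrational-frequency sine sequences):
# mean ~0, sd ~sqrt(1/2); used for synthetic GC and the fetal coverage
# signature so that every sample on a grid shares the same bin-level
# structure. Distinct frequencies give mutually uncorrelated tracks.
.binNoise <- function(n, freq = 2.399963230) sin(freq * seq_len(n))

#' Build a bin grid with synthetic GC content
#'
#' [makeBins()] plus a deterministic synthetic GC track (a smooth mixture of
#' sinusoids spanning roughly 0.34-0.54, emulating the GC range of real
#' 1 Mb bins). The same build and bin size always produce the identical
#' grid, so panels, cases and models built on it are comparable.
#'
#' @param build a \code{Seqinfo} (default [grch37()]).
#' @param binSize bin width in bp.
#' @return a [BinGrid-class] with GC annotated.
#' @export
simulateGrid <- function(build = grch37(), binSize = 1e6) {
  grid <- makeBins(build, binSize)
  n <- length(bins(grid))
  i <- seq_len(n)
  gc <- 0.44 + 0.06 * sin(i / 7.3) + 0.04 * sin(i / 131) +
    0.02 * .binNoise(n)
  b <- bins(grid)
  mcols(b)$gc <- pmin(pmax(gc, 0.25), 0.65)
  new("BinGrid", bins = b, binSize = binSize(grid))
}

#' Specify one simulated cfDNA sample
#'
#' Collects the generative parameters for [simulateCounts()]. Defaults are
#' the package's declared study conditions: negative-binomial
#' overdispersion 0.02 (fractional excess variance over Poisson), female
#' chrY mismap background mean 0.0015 / SD 0.0005, per-Y-copy chrY scale
#' \code{cY1 = 0.4}, fetal coverage-signature amplitude 0.10, no GC bias.
#'
#' @param grid a [BinGrid-class].
#' @param karyotype one of euploid / euploid-female / euploid-male, a
#'   trisomy label (\code{"T21"}, \code{"T13"}, ..., female fetus; append
#'   \code{"-male"} for a male fetus, e.g. \code{"T21-male"}), or X0 /
#'   XXX / XXY / XYY.
#' @param ff fetal fraction in [0,1].
#' @param nFragments expected binned fragments.
#' @param dispersion NB overdispersion (0 = Poisson).
#' @param gcBias \code{NULL} or \code{c(slope, center)}: bins get relative
#'   weight \code{1 + slope * (gc - center)}.
#' @param cnvs \code{NULL} or data.frame(chrom, start, end, copies) of fetal
#'   copy-number events (0-based half-open coordinates).
#' @param mismapMean,mismapSD female chrY mismap background.
#' @param cY1 chrY y-statistic per fetal Y copy at ff = 1.
#' @param signatureSD fetal coverage-signature amplitude.
#' @param seed RNG seed.
#' @param sampleID sample name.
#' @return a \code{SimulationConfig} (validated list).
#' @export
simulationConfig <- function(grid, karyotype = "euploid", ff = 0.1,
                             nFragments = 5e6,
                             dispersion = simulatorDefaults()$dispersion,
                             gcBias = NULL, cnvs = NULL,
                             mismapMean = simulatorDefaults()$mismapMean,
                             mismapSD = simulatorDefaults()$mismapSD,
                             cY1 = defaultCY1(),
                             signatureSD = simulatorDefaults()$signatureSD,
                             seed = 1, sampleID = karyotype) {
  stopifnot(is(grid, "BinGrid"), ff >= 0, ff <= 1, nFragments > 0,
            dispersion >= 0)
  info <- .karyotypeInfo(karyotype)
  if (info$sex == "male" && ff == 0)
    stop("inconsistent config: male-signature karyotype with ff = 0")
  if ((info$kX != 2 || !is.na(info$trisomy)) && ff == 0)
    stop("inconsistent config: fetal aneuploidy with ff = 0")
  if (!is.null(cnvs)) {
    stopifnot(all(c("chrom", "start", "end", "copies") %in% colnames(cnvs)))
    sl <- seqlengths(seqinfo(bins(grid)))
    for (r in seq_len(nrow(cnvs))) {
      if (!(cnvs$chrom[r] %in% names(sl)) || cnvs$start[r] < 0 ||
          cnvs$end[r] > sl[[cnvs$chrom[r]]] || cnvs$start[r] >= cnvs$end[r])
        stop("CNV region out of chromosome bounds")
      if (ff == 0) stop("inconsistent config: fetal CNV with ff = 0")
    }
  }
  structure(list(grid = grid, karyotype = karyotype, ff = ff,
                 nFragments = nFragments, dispersion = dispersion,
                 gcBias = gcBias, cnvs = cnvs, mismapMean = mismapMean,
                 mismapSD = mismapSD, cY1 = cY1, signatureSD = signatureSD,
                 seed = seed, sampleID = sampleID, info = info),
            class = "SimulationConfig")
}

#' Simulate one sample's binned counts
#'
#' Expected count for bin \eqn{b}:
#' \eqn{E_b \propto w_b \, d_b \, g(gc_b) (1 + f s_b)}, normalized to
#' \code{nFragments}, with \eqn{w_b} the usability weight, dosage
#' \eqn{d_b = 1 + f (k_b - 2)/2} for the bin's fetal copy number
#' \eqn{k_b}, \eqn{g} the configured GC bias, and \eqn{s_b} a fixed
#' per-grid fetal coverage signature (autosomes only). The chrY expected
#' fraction is a per-sample mismap background draw plus
#' \eqn{f \, k_Y \, c_{Y1}}, with the Y-specific part placed in the bins
#' overlapping the chrY marker genes (PAR excluded) and the background
#' spread uniformly along chrY. Counts are negative-binomial with variance
#' \eqn{(1 + \mathrm{dispersion}) \cdot \mu} (Poisson at dispersion 0).
#' Fully reproducible from the seed.
#'
#' @param config a [simulationConfig()].
#' @return a list of class \code{SimulatedSample}: \code{bc} (a
#'   [BinCounts-class]) and \code{truth} (karyotype, sex, ff, cnvs, seed).
#' @export
simulateCounts <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  grid <- config$grid
  b <- bins(grid)
  n <- length(b)
  chrom <- as.character(seqnames(b))
  usable <- mcols(b)$usable
  f <- config$ff
  info <- config$info

  k <- rep(2, n)
  if (!is.na(info$trisomy)) {
    hit <- .isChrom(chrom, info$trisomy)
    if (!any(hit)) stop("trisomy chromosome not in grid: ", info$trisomy)
    k[hit] <- 3
  }
  if (!is.null(config$cnvs)) {
    cn <- config$cnvs
    ov <- findOverlaps(b, GRanges(cn$chrom, IRanges(cn$start + 1, cn$end)))
    k[queryHits(ov)] <- cn$copies[subjectHits(ov)]
  }
  isX <- .isChrX(chrom); isY <- .isChrY(chrom)
  k[isX] <- info$kX

  w <- as.numeric(usable)
  g <- rep(1, n)
  if (!is.null(config$gcBias)) {
    gc <- mcols(b)$gc
    g <- pmax(1 + config$gcBias[1] * (gc - config$gcBias[2]), 0.05)
    g[is.na(g)] <- 1
  }
  s <- rep(0, n)
  auto <- .isAutosome(chrom)
  s[auto] <- config$signatureSD / sqrt(0.5) * .binNoise(n, freq = exp(1))[auto]
  rel <- w * .dosage(k, f) * g * pmax(1 + f * s, 0.1)
  rel[isY] <- 0

  yFrac <- 0
  p <- numeric(n)
  if (any(isY)) {
    mismap <- max(stats::rnorm(1, config$mismapMean, config$mismapSD), 0)
    ySignal <- f * info$kY * config$cY1
    yFrac <- mismap + ySignal
    yUse <- isY & usable
    if (any(yUse)) {
      p[yUse] <- mismap / sum(yUse)
      if (ySignal > 0) {
        geneBins <- .chrYMarkerBins(grid)
        if (!any(geneBins)) geneBins <- yUse
        p[geneBins] <- p[geneBins] + ySignal / sum(geneBins)
      }
    } else yFrac <- 0
  }
  p[!isY] <- rel[!isY] / sum(rel[!isY]) * (1 - yFrac)
  mu <- config$nFragments * p
  d <- config$dispersion
  counts <- numeric(n)
  pos <- mu > 0
  counts[pos] <- if (d == 0) stats::rpois(sum(pos), mu[pos])
    else stats::rnbinom(sum(pos), mu = mu[pos], size = mu[pos] / d)
  bc <- new("BinCounts", sampleID = config$sampleID, grid = grid,
            counts = counts, totalHQReads = sum(counts), mapqMin = 30,
            dedupPositions = FALSE)
  structure(list(bc = bc,
                 truth = list(karyotype = config$karyotype,
                              sex = info$sex, ff = f,
                              cnvs = config$cnvs, seed = config$seed)),
            class = "SimulatedSample")
}

.isChrom <- function(chrom, target)
  chrom == target | chrom == sub("^chr", "", target) |
  chrom == paste0("chr", target)

# chrY bins overlapping the marker genes, PAR-overlapping bins excluded.
.chrYMarkerBins <- function(grid) {
  b <- bins(grid)
  out <- rep(FALSE, length(b))
  genes <- tryCatch(chrYGeneRegions(), error = function(e) NULL)
  if (is.null(genes)) return(out)
  par <- tryCatch(parRegions(), error = function(e) NULL)
  ov <- IRanges::overlapsAny(b, regions(genes))
  if (!is.null(par)) ov <- ov & !IRanges::overlapsAny(b, regions(par))
  ov & .chrYBins(grid) & mcols(b)$usable
}

#' Simulate a reference cohort plus cases
#'
#' Reference samples are euploid-female pregnancies (fetal fraction drawn
#' uniformly from \code{ffRange}); cases follow the supplied configurations.
#' Every per-sample seed is derived deterministically from the master seed,
#' so a fixed master seed reproduces the cohort byte for byte.
#'
#' @param grid a [BinGrid-class].
#' @param nReference number of reference samples (>= 2; the benchmark
#'   control-set size in this framework is 140).
#' @param caseConfigs list of [simulationConfig()]s (seeds are re-derived).
#' @param seed master seed.
#' @param nFragments fragments per reference sample.
#' @param ffRange fetal-fraction range of reference samples.
#' @param ... further arguments passed to [simulationConfig()] for the
#'   reference samples (e.g. \code{dispersion}).
#' @return list with \code{reference} and \code{cases}, both lists of
#'   \code{SimulatedSample}.
#' @export
simulateCohort <- function(grid, nReference = 140, caseConfigs = list(),
                           seed = 1, nFragments = 5e6,
                           ffRange = c(0.04, 0.15), ...) {
  if (nReference < 2) stop("need >= 2 reference samples")
  set.seed(seed)
  nTot <- nReference + length(caseConfigs)
  seeds <- sample.int(.Machine$integer.max - 1, nTot)
  refFF <- stats::runif(nReference, ffRange[1], ffRange[2])
  reference <- lapply(seq_len(nReference), function(i) {
    cfg <- simulationConfig(grid, "euploid-female", ff = refFF[i],
                            nFragments = nFragments, seed = seeds[i],
                            sampleID = sprintf("ref_%03d", i), ...)
    simulateCounts(cfg)
  })
  cases <- lapply(seq_along(caseConfigs), function(j) {
    cfg <- caseConfigs[[j]]
    cfg$seed <- seeds[nReference + j]
    simulateCounts(cfg)
  })
  list(reference = reference, cases = cases)
}

#' Simulate chrY y-statistics directly
#'
#' The lightweight generator for the chrY sex statistic: female samples draw
#' only the mismap background (normal, truncated at 0); male samples add
#' \code{ff * cY1}. This is the statistic-level view of the same model
#' [simulateCounts()] uses for chrY.
#'
#' @param n number of samples.
#' @param sex "male"/"female", recycled to length \code{n}.
#' @param ff fetal fractions, recycled.
#' @param mismapMean,mismapSD,cY1 generative constants.
#' @param seed RNG seed.
#' @return data.frame with columns \code{sex}, \code{ff}, \code{y}.
#' @export
simulateYStatistics <- function(n, sex, ff,
                                mismapMean = simulatorDefaults()$mismapMean,
                                mismapSD = simulatorDefaults()$mismapSD,
                                cY1 = defaultCY1(), seed = 1) {
  set.seed(seed)
  sex <- rep_len(sex, n)
  ff <- rep_len(ff, n)
  base <- pmax(stats::rnorm(n, mismapMean, mismapSD), 0)
  y <- base + ifelse(sex == "male", ff * cY1, 0)
  data.frame(sex = sex, ff = ff, y = y)
}

#' Simulate a FASTQ file
#'
#' Random single-end reads with controllable length and quality
#' distributions and an injected exact-duplicate rate, for exercising the
#' read-level QC stage.
#'
#' @param path output FASTQ path.
#' @param nReads number of reads.
#' @param length read length (scalar, or vector sampled per read).
#' @param qMean,qSD per-base Phred quality distribution (clamped to [2,40]).
#' @param dupRate probability that a read is an exact copy of an earlier
#'   read.
#' @param seed RNG seed.
#' @return invisibly, the number of injected duplicates.
#' @export
simulateFastq <- function(path, nReads, length = 50, qMean = 32, qSD = 4,
                          dupRate = 0, seed = 1) {
  stopifnot(nReads > 0, qSD >= 0, dupRate >= 0, dupRate < 1)
  set.seed(seed)
  len <- if (base::length(length) == 1) rep(length, nReads)
         else sample(length, nReads, replace = TRUE)
  seqs <- vapply(len, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    "")
  quals <- vapply(len, function(L) {
    q <- pmin(pmax(round(stats::rnorm(L, qMean, qSD)), 2), 40)
    rawToChar(as.raw(q + 33))
  }, "")
  nDup <- 0L
  if (dupRate > 0 && nReads > 1) {
    isDup <- stats::runif(nReads) < dupRate
    isDup[1] <- FALSE
    for (i in which(isDup)) {
      j <- sample.int(i - 1, 1)
      seqs[i] <- seqs[j]; quals[i] <- quals[j]
    }
    nDup <- sum(isDup)
  }
  out <- character(4L * nReads)
  out[seq(1, by = 4, length.out = nReads)] <- sprintf("@read_%06d", seq_len(nReads))
  out[seq(2, by = 4, length.out = nReads)] <- seqs
  out[seq(3, by = 4, length.out = nReads)] <- "+"
  out[seq(4, by = 4, length.out = nReads)] <- quals
  writeLines(out, path)
  invisible(nDup)
}
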