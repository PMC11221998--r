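# A compact grid for fast panel arithmetic tests: 3 autosomes + X + Y.
panelGrid <- function() fixture("panelGrid", function()
  simulateGrid(genomeBuild("mini", c(chr1 = 60e6, chr2 = 50e6,
                                     chr3 = 40e6, chrX = 30e6,
                                     chrY = 10e6)), 1e6))

simBC <- function(karyotype = "euploid-female", ff = 0.08, n = 2e6,
                  seed = 1, grid = panelGrid(), ...) {
  simulateCounts(simulationConfig(grid, karyotype, ff = ff,
                                  nFragments = n, seed = seed, ...))$bc
}

test_that("GC correction is near-identity without GC bias and removes an injected trend", {
  # flat counts at high depth on a 10,000-bin grid
  lens <- setNames(rep(2e9, 5), paste0("chr", 1:5))
  grid <- simulateGrid(genomeBuild("flat", lens), 1e6)
  bc <- simulateCounts(simulationConfig(grid, "euploid", ff = 0,
    nFragments = 1e8, dispersion = 0, signatureSD = 0, seed = 2))$bc
  raw <- readCounts(bc) / sum(readCounts(bc))
  corr <- gcCorrect(bc)
  expect_lt(max(abs(corr - raw) / raw), 0.01)

  # injected linear GC bias: depth more than doubles across the GC range
  gc <- GenomicRanges::mcols(bins(grid))$gc
  bcB <- simulateCounts(simulationConfig(grid, "euploid", ff = 0,
    nFragments = 1e8, dispersion = 0, signatureSD = 0,
    gcBias = c(1 / 0.3, 0.45), seed = 3))$bc
  rawB <- readCounts(bcB) / sum(readCounts(bcB))
  slopeRaw <- coef(lm(rawB / mean(rawB) ~ gc))[2]
  corrB <- gcCorrect(bcB)
  slopeCorr <- coef(lm(corrB / mean(corrB) ~ gc))[2]
  expect_gt(abs(slopeRaw), 1)            # bias clearly present before
  expect_lt(abs(slopeCorr), 0.05)        # and flat after

  # degenerate input: a single nonzero bin cannot support a trend fit
  cnt <- numeric(length(bins(grid))); cnt[5] <- 1000
  one <- new("BinCounts", sampleID = "deg", grid = grid, counts = cnt,
             totalHQReads = 1000, mapqMin = 30, dedupPositions = FALSE)
  expect_error(gcCorrect(one), "degenerate")
})

test_that("panel construction blacklists degenerate bins and rejects bad input", {
  bc1 <- simBC(seed = 10)
  expect_error(buildPanel(list(bc1)), ">= 2")
  # identical samples: SD 0 everywhere -> all bins blacklisted, unusable
  p <- suppressWarnings(buildPanel(list(bc1, bc1, bc1)))
  expect_true(all(blacklistedBins(p)))
  expect_false(p@usable)
  expect_error(profileSample(bc1, p), "unusable")
  # grid mismatch
  other <- simBC(grid = simulateGrid(genomeBuild("o", c(chr1 = 5e6)), 1e6),
                 seed = 11)
  expect_error(buildPanel(list(bc1, other)), "grid mismatch")
})

test_that("panel recovers simulation truth and z-scores are standard normal", {
  fx <- aneuploidyCohort()
  panel <- fx$panel
  expect_equal(panel@nSamples, 140L)
  # per-chromosome mean fractions close to the generative expectation
  b <- bins(fx$grid)
  auto <- grepl("^chr[0-9]+$", as.character(seqnames(b)))
  nAuto <- table(as.character(seqnames(b))[auto])
  cs <- panel@chromStats
  for (ch in c("chr1", "chr13", "chr21")) {
    truth <- nAuto[[ch]] / sum(nAuto)
    se <- cs$sdFrac[cs$chrom == ch] / sqrt(140)
    expect_lt(abs(cs$meanFrac[cs$chrom == ch] - truth), 3 * se + 1e-4)
  }
  # a fresh euploid sample: per-bin z approximately standard normal
  bc <- simulateCounts(simulationConfig(fx$grid, "euploid-female",
    ff = 0.10, nFragments = 5e6, seed = 777))$bc
  prof <- profileSample(bc, panel)
  zAuto <- prof@z[auto & !blacklistedBins(panel)]
  expect_lt(abs(mean(zAuto, na.rm = TRUE)), 0.1)
  expect_gt(sd(zAuto, na.rm = TRUE), 0.85)
  expect_lt(sd(zAuto, na.rm = TRUE), 1.15)
})

test_that("profiles have exact log2/z semantics at the panel reference point", {
  fx <- aneuploidyCohort()
  panel <- fx$panel
  grid <- fx$grid
  # a synthetic sample whose corrected depth equals the panel mean has
  # log2 = 0 and z = 0; +3 SD in depth space gives z = 3; 2x gives log2 = 1
  nb <- length(bins(grid))
  fake <- new("SampleProfile", sampleID = "exact", grid = grid,
              depth = panel@binMean,
              log2Ratio = log2(panel@binMean / panel@binMean),
              z = (panel@binMean - panel@binMean) / panel@binSD)
  expect_true(all(fake@log2Ratio == 0))
  expect_true(all(fake@z == 0))
  obs <- panel@binMean + 3 * panel@binSD
  expect_equal((obs - panel@binMean) / panel@binSD, rep(3, nb))
  expect_equal(log2((2 * panel@binMean) / panel@binMean), rep(1, nb))
})

test_that("log2 ratios and z-scores are invariant to sequencing depth", {
  fx <- aneuploidyCohort()
  bc <- simulateCounts(simulationConfig(fx$grid, "euploid-female",
    ff = 0.08, nFragments = 5e6, seed = 31))$bc
  scaled <- new("BinCounts", sampleID = "x7", grid = fx$grid,
                counts = readCounts(bc) * 7,
                totalHQReads = bc@totalHQReads * 7, mapqMin = 30,
                dedupPositions = FALSE)
  p1 <- profileSample(bc, fx$panel)
  p2 <- profileSample(scaled, fx$panel)
  ok <- !is.na(p1@z)
  expect_lt(max(abs(p1@z[ok] - p2@z[ok])), 1e-9)
  expect_lt(max(abs(p1@log2Ratio[ok] - p2@log2Ratio[ok])), 1e-9)
})

test_that("panel statistics are invariant to sample order", {
  samples <- lapply(1:6, function(i) simBC(seed = 40 + i))
  p1 <- buildPanel(samples)
  p2 <- buildPanel(rev(samples))
  expect_equal(p1@binMean, p2@binMean)
  expect_equal(p1@binSD, p2@binSD)
  expect_equal(p1@chromStats, p2@chromStats)
})
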