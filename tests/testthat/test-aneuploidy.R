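# A hand-built panel/profile pair lets the consensus contract be tested
# with exactly controlled statistics.
mkToy <- function() {
  grid <- makeBins(genomeBuild("mini", c(chr1 = 1e7, chr2 = 1e7)), 1e6)
  nb <- length(bins(grid))
  panel <- new("ReferencePanel", grid = grid, nSamples = 10L,
               binMean = rep(0.05, nb), binSD = rep(0.005, nb),
               blacklist = rep(FALSE, nb),
               chromStats = data.frame(chrom = c("chr1", "chr2"),
                                       meanFrac = c(0.5, 0.5),
                                       sdFrac = c(0.01, 0.01)),
               yMean = NA_real_, ySD = NA_real_, geneYMean = NA_real_,
               geneYSD = NA_real_, cY1 = 0.4, usable = TRUE)
  list(grid = grid, panel = panel)
}
mkProfile <- function(grid, z) new("SampleProfile", sampleID = "t",
  grid = grid, depth = rep(0.05, length(z)), log2Ratio = z * 0.01, z = z)
mkCounts <- function(grid, frac1) {
  counts <- c(rep(1000 * frac1, 10), rep(1000 * (1 - frac1), 10))
  new("BinCounts", sampleID = "t", grid = grid, counts = counts,
      totalHQReads = sum(counts), mapqMin = 30, dedupPositions = FALSE)
}

test_that("fraction z-score follows (observed - mean)/SD exactly", {
  toy <- mkToy()
  bc <- mkCounts(toy$grid, 0.53)   # fraction 0.53 vs mean 0.5, SD 0.01
  expect_equal(chromZFraction(bc, toy$panel, "chr1"), 3.0)
  expect_equal(chromZFraction(bc, toy$panel, "chr2"), -3.0)
  bcNull <- mkCounts(toy$grid, 0.5)
  expect_equal(chromZFraction(bcNull, toy$panel, "chr1"), 0)
  badPanel <- mkToy()$panel
  badPanel@chromStats$sdFrac <- c(0, 0.01)
  expect_error(chromZFraction(bc, badPanel, "chr1"), "SD is zero")
  expect_error(chromZFraction(bc, toy$panel, "chr9"), "no fraction")
})

test_that("Stouffer aggregation equals sum/sqrt(n) and handles blacklists", {
  toy <- mkToy()
  # 10 bins of z = 1 on chr1 -> Z = 10/sqrt(10); all-zero -> 0
  prof <- mkProfile(toy$grid, c(rep(1, 10), rep(0, 10)))
  expect_equal(chromZStouffer(prof, "chr1"), sqrt(10))
  expect_equal(chromZStouffer(prof, "chr2"), 0)
  # 49 bins of z = 1 -> 7 (derived from the direct formula)
  g49 <- makeBins(genomeBuild("one", c(chr1 = 49e6)), 1e6)
  p49 <- new("SampleProfile", sampleID = "t", grid = g49,
             depth = rep(1, 49), log2Ratio = rep(0, 49), z = rep(1, 49))
  expect_equal(chromZStouffer(p49, "chr1"), 7.0)
  # random vectors agree with the brute-force oracle to 1e-12
  set.seed(11)
  for (i in 1:20) {
    z <- rnorm(20)
    prof <- mkProfile(toy$grid, z)
    oracle <- sum(z[1:10]) / sqrt(10)
    expect_equal(chromZStouffer(prof, "chr1"), oracle, tolerance = 1e-12)
  }
  # NA (blacklisted) bins are dropped from both sum and n
  z <- c(rep(2, 5), rep(NA, 5), rep(0, 10))
  expect_equal(chromZStouffer(mkProfile(toy$grid, z), "chr1"),
               10 / sqrt(5))
  zAllNA <- c(rep(NA, 10), rep(0, 10))
  expect_error(chromZStouffer(mkProfile(toy$grid, zAllNA), "chr1"),
               "blacklisted")
})

test_that("consensus calling requires both methods to cross the threshold", {
  toy <- mkToy()
  # fraction method crosses on chr1 (z=5), Stouffer stays null -> no call
  bc <- mkCounts(toy$grid, 0.55)
  prof <- mkProfile(toy$grid, rep(0, 20))
  calls <- callAutosomes(bc, prof, toy$panel, zThreshold = 3)
  expect_equal(calls$call[calls$chrom == "chr1"], "no_consensus")
  expect_equal(calls$call[calls$chrom == "chr2"], "no_consensus")

  # both cross positively -> trisomy; both negative -> monosomy
  prof2 <- mkProfile(toy$grid, c(rep(2, 10), rep(-2, 10)))
  calls2 <- callAutosomes(bc, prof2, toy$panel, zThreshold = 3)
  expect_equal(calls2$call, c("trisomy", "monosomy"))
  expect_equal(calls2$note[2], "rarely reportable")

  # discordant directions are surfaced, not resolved
  bc3 <- mkCounts(toy$grid, 0.55)
  prof3 <- mkProfile(toy$grid, c(rep(-2, 10), rep(2, 10)))
  calls3 <- callAutosomes(bc3, prof3, toy$panel, zThreshold = 3)
  expect_true(all(calls3$call == "no_consensus"))

  # nothing crosses -> normal
  calls4 <- callAutosomes(mkCounts(toy$grid, 0.505),
                          mkProfile(toy$grid, rep(0.3, 20)), toy$panel)
  expect_true(all(calls4$call == "normal"))
})

test_that("euploid fraction z-scores behave like a standard normal", {
  fx <- aneuploidyCohort()
  zs <- vapply(1:200, function(i) {
    bc <- simulateCounts(simulationConfig(fx$grid, "euploid-female",
      ff = runif(1, 0.04, 0.15), nFragments = 5e6, seed = 5000 + i))$bc
    chromZFraction(bc, fx$panel, "chr21")
  }, 0)
  expect_lt(abs(mean(zs)), 0.15)
  expect_gt(sd(zs), 0.8)
  expect_lt(sd(zs), 1.2)
})

test_that("trisomy and monosomy of equal fetal fraction give symmetric z", {
  fx <- aneuploidyCohort()
  ff <- 0.10
  tri <- simulateCounts(simulationConfig(fx$grid, "T18", ff = ff,
    nFragments = 5e6, seed = 61))$bc
  mono <- simulateCounts(simulationConfig(fx$grid, "euploid-female",
    ff = ff, nFragments = 5e6, seed = 61,
    cnvs = data.frame(chrom = "chr18", start = 0, end = 78077248,
                      copies = 1)))$bc
  zT <- chromZFraction(tri, fx$panel, "chr18")
  zM <- chromZFraction(mono, fx$panel, "chr18")
  expect_gt(zT, 3)
  expect_lt(zM, -3)
  expect_lt(abs(abs(zT) - abs(zM)) / abs(zT), 0.25)
})
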