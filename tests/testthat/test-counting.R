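toyCountGrid <- function() makeBins(genomeBuild("toy",
  c(chr1 = 5e6, chrY = 2e6)), 1e6)

test_that("binned counting excludes low-MAPQ reads and uses leftmost position", {
  grid <- toyCountGrid()
  set.seed(1)
  bam <- samToBam(c(
    samRecord("chr1", 100, mapq = 60),
    samRecord("chr1", 999999, mapq = 60),  # 10M span crosses into bin 2
    samRecord("chr1", 1000001, mapq = 60),
    samRecord("chr1", 500, mapq = 10),     # below cutoff
    samRecord("chrY", 100, mapq = 60)))
  bc <- binCountsFromBam(bam, grid, mapqMin = 30)
  expect_equal(sum(readCounts(bc)), 4)
  expect_equal(bc@totalHQReads, 4)
  # leftmost-position rule: read at 999,999 belongs to bin 1 only
  expect_equal(readCounts(bc)[1], 2)
  expect_equal(readCounts(bc)[2], 1)
  expect_equal(readCounts(bc)[6], 1)       # chrY bin 1
})

test_that("empty BAM gives all-zero counts; missing chromosomes error", {
  grid <- toyCountGrid()
  bam <- samToBam(character(0))
  bc <- binCountsFromBam(bam, grid)
  expect_equal(sum(readCounts(bc)), 0)
  expect_equal(bc@totalHQReads, 0)

  set.seed(2)
  bamOther <- samToBam(samRecord("chrQ", 10), seqinfo = c(chrQ = 1e6))
  expect_error(binCountsFromBam(bamOther, grid), "no overlapping")
})

test_that("counting matches a brute-force per-read scan and is deterministic", {
  grid <- toyCountGrid()
  set.seed(3)
  n <- 500
  rname <- sample(c("chr1", "chrY"), n, replace = TRUE,
                  prob = c(0.8, 0.2))
  pos <- ifelse(rname == "chr1", sample.int(5e6 - 20, n, replace = TRUE),
                sample.int(2e6 - 20, n, replace = TRUE))
  mapq <- sample(c(0, 20, 40, 60), n, replace = TRUE)
  bam <- samToBam(mapply(samRecord, rname, pos, mapq,
                         qname = sprintf("q%04d", seq_len(n))))
  for (cut in c(0, 30, 50)) {
    bc <- binCountsFromBam(bam, grid, mapqMin = cut)
    b <- bins(grid)
    # oracle: test each passing read against each bin
    expected <- vapply(seq_along(b), function(i) {
      sum(mapq >= cut & rname == as.character(seqnames(b))[i] &
            pos >= start(b)[i] & pos <= end(b)[i])
    }, 0)
    expect_equal(readCounts(bc), expected)
  }
  # monotonicity: raising the cutoff never increases a bin count
  c30 <- readCounts(binCountsFromBam(bam, grid, mapqMin = 30))
  c50 <- readCounts(binCountsFromBam(bam, grid, mapqMin = 50))
  expect_true(all(c50 <= c30))
  # determinism
  expect_identical(readCounts(binCountsFromBam(bam, grid, mapqMin = 30)),
                   c30)
})

test_that("position dedup keeps one read per (chrom, position, strand)", {
  grid <- toyCountGrid()
  bam <- samToBam(c(
    samRecord("chr1", 1000, qname = "a"),
    samRecord("chr1", 1000, qname = "b"),            # same pos + strand
    samRecord("chr1", 1000, flag = 16, qname = "c"), # reverse strand kept
    samRecord("chr1", 2000, qname = "d")))
  bc <- binCountsFromBam(bam, grid, dedupPositions = TRUE)
  expect_equal(sum(readCounts(bc)), 3)
})

test_that("chromosome fractions sum to one and support the autosomal denominator", {
  grid <- toyCountGrid()
  mkbc <- function(counts) new("BinCounts", sampleID = "s", grid = grid,
                               counts = counts, totalHQReads = sum(counts),
                               mapqMin = 30, dedupPositions = FALSE)
  # all reads on chr1
  counts <- c(rep(10, 5), rep(0, 2))
  expect_equal(chromFractions(mkbc(counts))[["chr1"]], 1.0)
  expect_equal(chromFractions(mkbc(counts))[["chrY"]], 0.0)
  # equal split
  counts <- c(rep(10, 5), 25, 25)
  fr <- chromFractions(mkbc(counts))
  expect_equal(unname(fr), c(0.5, 0.5))
  # random counts: fractions sum to 1 within 1e-12 (direct-summation oracle)
  set.seed(4)
  for (i in 1:20) {
    counts <- rpois(7, 50) + 1
    fr <- chromFractions(mkbc(counts))
    expect_lt(abs(sum(fr) - 1), 1e-12)
  }
  # autosomal denominator: chrY fraction is relative to chr1 reads
  counts <- c(rep(10, 5), 25, 25)
  frA <- chromFractions(mkbc(counts), denominator = "autosomal")
  expect_equal(frA[["chrY"]], 1.0)
  expect_error(chromFractions(mkbc(rep(0, 7))), "zero")
})

test_that("region counting respects exclusion masks and overlapping labels", {
  regions <- new("RegionSet", name = "test", regions = GRanges(
    c("chrY", "chrY", "chrY"), IRanges(c(1001, 5001, 5501),
                                       c(2000, 6000, 6500)),
    label = c("geneA", "geneB", "geneC")))
  excl <- new("RegionSet", name = "mask", regions = GRanges(
    "chrY", IRanges(1501, 1600), label = "PARlike"))
  set.seed(5)
  bam <- samToBam(c(
    samRecord("chrY", 1100, qname = "inA"),
    samRecord("chrY", 1550, qname = "masked"),    # inside exclude
    samRecord("chrY", 5600, qname = "inBC"),      # in geneB AND geneC
    samRecord("chrY", 9000, qname = "outside")))
  rc <- regionCountsFromBam(bam, regions, exclude = excl)
  expect_equal(unname(rc@counts[c("geneA", "geneB", "geneC")]), c(1, 1, 1))
  # the overlapping read counts once per containing label, once in union
  expect_equal(regionUnionCount(rc), 2)
  expect_equal(rc@denominator, 4)
  expect_error(regionCountsFromBam(bam,
    new("RegionSet", name = "none", regions = GRanges(label = character(0)))),
    "empty")
})

test_that("bin-resolution region counts aggregate gene-overlapping bins", {
  grid <- toyCountGrid()
  counts <- c(rep(100, 5), 40, 7)
  bc <- new("BinCounts", sampleID = "s", grid = grid, counts = counts,
            totalHQReads = sum(counts), mapqMin = 30,
            dedupPositions = FALSE)
  regions <- new("RegionSet", name = "g", regions = GRanges(
    "chrY", IRanges(500001, 600000), label = "geneA"))
  rc <- regionCountsFromBins(bc, regions)
  expect_equal(unname(rc@counts[["geneA"]]), 40)    # chrY bin 1
  excl <- new("RegionSet", name = "m", regions = GRanges(
    "chrY", IRanges(1, 700000), label = "PAR"))
  rc2 <- regionCountsFromBins(bc, regions, exclude = excl)
  expect_equal(regionUnionCount(rc2), 0)
})

test_that("BinCounts TSV round-trips", {
  grid <- toyCountGrid()
  bc <- new("BinCounts", sampleID = "rt", grid = grid,
            counts = c(5, 0, 3, 1, 2, 9, 4), totalHQReads = 30,
            mapqMin = 30, dedupPositions = TRUE)
  f <- tempfile()
  writeBinCounts(bc, f)
  rt <- readBinCounts(f, grid)
  expect_equal(readCounts(rt), readCounts(bc))
  expect_equal(rt@totalHQReads, 30)
  expect_equal(sampleID(rt), "rt")
  expect_true(rt@dedupPositions)
})
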