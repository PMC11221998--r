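test_that("counts are reproducible from the seed and conserve the fragment total", {
  grid <- grch37Grid()
  cfg <- simulationConfig(grid, "T21", ff = 0.1, nFragments = 2e6,
                          seed = 123)
  s1 <- simulateCounts(cfg)
  s2 <- simulateCounts(cfg)
  expect_identical(readCounts(s1$bc), readCounts(s2$bc))
  expect_identical(s1$truth, s2$truth)
  # NB marginals: total within 3 SD of nFragments
  d <- simulatorDefaults()$dispersion
  sdTot <- sqrt((1 + d) * 2e6)
  expect_lt(abs(sum(readCounts(s1$bc)) - 2e6), 3 * sdTot)
})

test_that("Poisson counts match their expectation bin by bin", {
  grid <- grch37Grid()
  s <- simulateCounts(simulationConfig(grid, "euploid-female", ff = 0,
    nFragments = 1e7, dispersion = 0, signatureSD = 0, seed = 5))
  cnt <- readCounts(s$bc)
  b <- bins(grid)
  auto <- grepl("^chr[0-9]+$", as.character(seqnames(b)))
  mu <- mean(cnt[auto])           # uniform weights -> common expectation
  z <- (cnt[auto] - mu) / sqrt(mu)
  expect_lt(max(abs(z)), 5)       # every bin within 5 SD of Poisson
})

test_that("trisomy dosage follows 1 + f/2 at the affected chromosome", {
  grid <- grch37Grid()
  s <- simulateCounts(simulationConfig(grid, "T21", ff = 0.20,
    nFragments = 1e7, dispersion = 0, signatureSD = 0, seed = 6))
  cnt <- readCounts(s$bc)
  chrom <- as.character(seqnames(bins(grid)))
  auto <- grepl("^chr[0-9]+$", chrom)
  base <- mean(cnt[auto & chrom != "chr21"])
  ratio <- mean(cnt[chrom == "chr21"]) / base
  expect_lt(abs(ratio - 1.10), 0.005 * 1.10)
  expect_equal(s$truth$karyotype, "T21")
  expect_equal(s$truth$sex, "female")
})

test_that("sex-chromosome dosage and chrY signal follow the karyotype", {
  grid <- grch37Grid()
  chrom <- as.character(seqnames(bins(grid)))
  auto <- grepl("^chr[0-9]+$", chrom)
  yLevel <- function(kar, ff) {
    s <- simulateCounts(simulationConfig(grid, kar, ff = ff,
      nFragments = 4e6, dispersion = 0, signatureSD = 0,
      mismapSD = 0, seed = 8))
    sum(readCounts(s$bc)[chrom == "chrY"]) / sum(readCounts(s$bc))
  }
  xDosage <- function(kar, ff) {
    s <- simulateCounts(simulationConfig(grid, kar, ff = ff,
      nFragments = 1e7, dispersion = 0, signatureSD = 0, seed = 9))
    cnt <- readCounts(s$bc)
    (mean(cnt[chrom == "chrX"]) / mean(cnt[auto]))
  }
  # XY male at ff=0.1: chrY fraction ~ mismap + 0.1*0.4 = 0.0415
  expect_lt(abs(yLevel("euploid-male", 0.10) - 0.0415), 0.002)
  # XYY doubles the Y-specific part
  expect_lt(abs(yLevel("XYY", 0.10) - 0.0815), 0.003)
  # chrX dosage: male 1 - f/2; XXX 1 + f/2; X0 1 - f/2 (female)
  expect_lt(abs(xDosage("euploid-male", 0.2) - 0.9), 0.01)
  expect_lt(abs(xDosage("XXX", 0.2) - 1.1), 0.01)
  expect_lt(abs(xDosage("X0", 0.2) - 0.9), 0.01)
  # inconsistent configs are rejected
  expect_error(simulationConfig(grid, "XYY", ff = 0), "inconsistent")
  expect_error(simulationConfig(grid, "T21", ff = 0), "inconsistent")
})

test_that("CNV events modulate exactly the covered bins", {
  grid <- grch37Grid()
  cnv <- data.frame(chrom = "chr2", start = 100e6, end = 103e6, copies = 3)
  s <- simulateCounts(simulationConfig(grid, "euploid-female", ff = 0.2,
    nFragments = 2e7, dispersion = 0, signatureSD = 0, cnvs = cnv,
    seed = 10))
  cnt <- readCounts(s$bc)
  b <- bins(grid)
  chrom <- as.character(seqnames(b))
  inEvent <- chrom == "chr2" & start(b) >= 100e6 + 1 & end(b) <= 103e6
  outEvent <- chrom == "chr2" & !inEvent
  expect_equal(sum(inEvent), 3L)
  ratio <- mean(cnt[inEvent]) / mean(cnt[outEvent])
  expect_lt(abs(ratio - 1.10), 0.02)
  expect_error(simulationConfig(grid, "euploid", ff = 0.1, cnvs =
    data.frame(chrom = "chr2", start = -5, end = 100, copies = 3)),
    "bounds")
})

test_that("cohorts are deterministic and labelled with ground truth", {
  grid <- grch37Grid()
  mk <- function() simulateCohort(grid, nReference = 3,
    caseConfigs = list(simulationConfig(grid, "T21", ff = 0.1,
                                        nFragments = 1e6)),
    seed = 77, nFragments = 1e6)
  c1 <- mk(); c2 <- mk()
  expect_length(c1$reference, 3)
  expect_length(c1$cases, 1)
  expect_equal(c1$cases[[1]]$truth$karyotype, "T21")
  expect_identical(lapply(c1$reference, function(s) readCounts(s$bc)),
                   lapply(c2$reference, function(s) readCounts(s$bc)))
  expect_identical(readCounts(c1$cases[[1]]$bc),
                   readCounts(c2$cases[[1]]$bc))
  # reference truth is euploid female
  expect_true(all(vapply(c1$reference, function(s)
    s$truth$karyotype == "euploid-female" & s$truth$sex == "female", TRUE)))
  expect_error(simulateCohort(grid, nReference = 1, seed = 1), ">= 2")
})

test_that("the y-statistic generator matches its stated model", {
  d <- simulateYStatistics(2000, rep(c("male", "female"), 1000),
                           ff = 0.1, seed = 42)
  m <- d$y[d$sex == "male"]; f <- d$y[d$sex == "female"]
  expect_lt(abs(mean(f) - 0.0015), 3 * 0.0005 / sqrt(1000))
  expect_lt(abs(mean(m) - (0.0015 + 0.1 * 0.4)), 3 * 0.0005 / sqrt(1000))
  expect_true(all(d$y >= 0))
  expect_identical(simulateYStatistics(50, "male", 0.05, seed = 9),
                   simulateYStatistics(50, "male", 0.05, seed = 9))
})

test_that("simulated FASTQ honours the length grid and duplicates injection", {
  fq <- tempfile(fileext = ".fastq")
  simulateFastq(fq, nReads = 200, length = 30, seed = 3)
  res <- filterReads(fq)           # min length 35 downstream
  expect_equal(res$stats$readsOut, 0L)
  expect_equal(res$stats$removedShort, 200L)
  # fixed seed -> identical stream
  fq2 <- tempfile(fileext = ".fastq")
  simulateFastq(fq2, nReads = 200, length = 30, seed = 3)
  expect_identical(readLines(fq), readLines(fq2))
})
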