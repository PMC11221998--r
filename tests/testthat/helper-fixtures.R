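# Shared fixtures, built once per test run and memoised.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, builder(), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

toyBuild <- function() genomeBuild("toy", c(chrA = 2.5e6, chrB = 1e6))

# GRCh37 1 Mb grid with synthetic GC, shared across files.
grch37Grid <- function() fixture("grch37Grid", function() simulateGrid())

# The benchmark cohort: 140 euploid-female references (5M fragments) plus
# 15 trisomy cases (five each T13/T18/T21, ff uniform 0.04-0.15), master
# seed 1, and the panel built from the references.
aneuploidyCohort <- function() fixture("aneuploidyCohort", function() {
  grid <- grch37Grid()
  set.seed(1001)
  ffs <- runif(15, 0.04, 0.15)
  kars <- rep(c("T13", "T18", "T21"), each = 5)
  cases <- lapply(seq_len(15), function(i)
    simulationConfig(grid, kars[i], ff = ffs[i], nFragments = 5e6,
                     sampleID = sprintf("case_%s_%02d", kars[i], i)))
  coh <- simulateCohort(grid, nReference = 140, caseConfigs = cases,
                        seed = 1, nFragments = 5e6)
  panel <- buildPanel(lapply(coh$reference, `[[`, "bc"),
                      regions = chrYGeneRegions())
  list(grid = grid, cohort = coh, panel = panel, caseKaryotype = kars,
       caseFF = ffs)
})

# Write SAM records (character vector of alignment lines) against a header,
# convert to sorted+indexed BAM, return the BAM path.
samToBam <- function(records, seqinfo = c(chr1 = 5e6, chrY = 2e6)) {
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqinfo),
                   as.integer(seqinfo)))
  writeLines(c(hdr, records), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

samRecord <- function(rname, pos, mapq = 60, flag = 0, seq = "ACGTACGTAC",
                      qname = NULL) {
  if (is.null(qname)) qname <- sprintf("r_%s_%d_%d", rname, pos,
                                       sample.int(1e6, 1))
  sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
          qname, flag, rname, pos, mapq, nchar(seq), seq,
          strrep("I", nchar(seq)))
}
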