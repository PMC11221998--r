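# shallowNIPT

Noninvasive prenatal testing (NIPT) screens for fetal chromosomal
abnormalities by shallow whole-genome sequencing of maternal plasma
cell-free DNA (cfDNA), a mixture in which a fraction *f* (the **fetal
fraction**) is of placental origin. A locus with fetal copy number *k*
then has expected relative depth `1 + f·(k−2)/2`, so a fetal trisomy
lifts a whole chromosome's read share by `f/2` — a percent-scale effect
recoverable by binning reads, correcting GC bias, and z-scoring each
sample against a reference panel of confirmed-normal pregnancies.

`shallowNIPT` is an R/Bioconductor-style implementation of the complete
analysis layer for laboratory bioinformaticians building or validating an
NIPT pipeline:

* **Read QC** — length / mean-quality / duplicate filtering of FASTQ, and
  the sample gate (≥ 1.5 M high-quality reads, fetal fraction ≥ 4%).
* **Counting** — BAM to per-bin counts (leftmost position, MAPQ ≥ 30,
  optional position dedup), chromosome fractions, region counts.
* **Reference panel** — per-bin and per-chromosome location/scale
  statistics with blacklisting; lowess GC correction; per-bin
  `log2(obs/exp)` and z profiles.
* **Aneuploidy** — dual statistics per autosome (Stouffer
  `Z = Σz/√n` and the chromosome-fraction z) with a consensus rule at
  `|z| ≥ 3`; disagreement is surfaced as `no_consensus`, never resolved
  silently.
* **Fetal sex & SCA** — the chrY read-ratio method (threshold 0.01) and
  the seven chrY marker-gene method (PAR excluded); XXX/X0 by chrX
  fraction z; XY/XXY/XYY by a standardized-distance classifier over
  (chrX z, chrY gene level).
* **Fetal fraction** — chrY scaling between female-background and
  one-Y-copy calibration points; an elastic-net regressor on autosomal
  bin depths for either sex.
* **CNV** — recursive interval (CBS-style) segmentation of per-bin
  z-scores, calls at ≥ 1 Mb and `|Z| ≥ 3`, with expected fetal magnitudes
  `±log2(1 ± f/2)` annotated.
* **Reporting** — a JSON `KaryotypeReport`, circos-style z / log2 track
  export, confusion-matrix metrics (PPV/NPV/sensitivity/specificity).
* **Simulator** — a negative-binomial cfDNA cohort generator sharing the
  callers' dosage model (trisomies, SCAs, CNV events, chrY mismap
  background, GC bias, fetal coverage signature), so every stage is
  testable without patient data.

## Worked example

Simulate a 140-sample reference panel and a male trisomy-21 pregnancy at
10% fetal fraction, then run the full pipeline:

```r
library(shallowNIPT)

grid   <- simulateGrid()                  # GRCh37, 1 Mb bins, synthetic GC
cohort <- simulateCohort(grid, nReference = 140, seed = 20)
panel  <- buildPanel(lapply(cohort$reference, `[[`, "bc"),
                     regions = chrYGeneRegions())
panel
#> ReferencePanel: 140 samples, 3113 bins (0 blacklisted)

sample <- simulateCounts(simulationConfig(grid, "T21-male", ff = 0.10,
                                          nFragments = 1e7, seed = 21))
report <- runPipeline(sample$bc, panel)
report
#> KaryotypeReport for 'T21-male'
#>   QC: pass
#>   sex: male (chrY ratio 0.0419); ff: 0.101
#>   autosomes: chr21 trisomy
#>   sex karyotype: XY
```

Reading the output: the chrY ratio 0.0419 is far above the 0.01 sex
threshold (male); the fetal fraction estimated from that ratio, 0.101,
recovers the simulated truth of 0.10; chr21 crosses `z ≥ 3` by **both**
the Stouffer and the fraction statistic (consensus trisomy) while the
other 21 autosomes stay normal; and the male SCA classifier places the
sample at XY. `writeKaryotypeReport()`
serializes the whole report as JSON; `circosExport()` writes the per-bin
z (inner ring) and log2-ratio (outer ring) tracks for circos plotting.

A thin command-line wrapper over the same functions ships in
`inst/scripts/nipt` (subcommands `qc`, `count`, `simulate`, `analyze`,
`metrics`, `circos`; exit code 3 flags a QC-failed sample).

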