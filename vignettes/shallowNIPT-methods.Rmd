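---
title: "Statistical methods behind shallowNIPT"
author: "shallowNIPT authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind shallowNIPT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shallowNIPT)
```

# The problem and the dosage model

Noninvasive prenatal testing (NIPT) infers fetal chromosomal status from
shallow whole-genome sequencing of maternal plasma cell-free DNA (cfDNA).
Plasma cfDNA is a mixture: a fraction $f$ (the *fetal fraction*, typically
4--20%) originates from the placenta and carries the fetal genotype, the
rest is maternal. A locus present in $k$ copies in the fetal genome and two
copies in the mother therefore has expected relative depth

$$ d(k, f) \;=\; (1-f)\cdot 1 + f\cdot \frac{k}{2} \;=\; 1 + f\,\frac{k-2}{2}, $$

so a fetal trisomy ($k=3$) raises a whole chromosome's depth by $f/2$ — a
1--10% effect that is invisible per locus but detectable when reads are
aggregated into fixed-width bins and compared against a reference panel of
confirmed-normal pregnancies. Everything in this package is built on that
single dosage formula; the simulator and the callers share it
(`shallowNIPT:::.dosage`), so recovery tests cannot drift out of sync with
the calling model.

# From reads to normalized profiles

**Binning.** Reads are counted into non-overlapping bins (1 Mb by default
for aneuploidy work, 100 kb for CNV mode) by the leftmost aligned position
of each primary, MAPQ-passing alignment. MAPQ $\ge 30$ defines
"high-quality"; it is a conventional proxy for unique mapping and is
configurable. Bins are 0-based half-open internally; BED input is native
and 1-based Bioconductor ranges are converted at the boundary, so there is
exactly one coordinate convention per layer.

**GC correction.** Library preparation biases depth smoothly in bin GC
content. Each sample's normalized depths (bin count over the autosomal
binned total) are divided by a lowess trend of depth on GC (span 0.3)
fitted over usable autosomal bins, then rescaled to preserve the raw mean.
The sex chromosomes are corrected with the autosomal trend: fitting them
directly would absorb precisely the fetal dosage signal the sex-chromosome
callers need.

**Reference panel.** The panel stores, over $n \ge 2$ healthy-pregnancy
samples (the benchmark configuration uses 140), the per-bin mean and SD of
GC-corrected depth and the per-chromosome mean and SD of chromosome
fractions. Bins are blacklisted when unusable on the grid (e.g. >50% N),
zero in more than 10% of panel samples, or variance-degenerate; the
blacklist propagates as `NA` through every profile. A sample profiled
against the panel yields per-bin $z_b = (x_b - \hat\mu_b)/\hat\sigma_b$ and
$\log_2(x_b/\hat\mu_b)$; both are invariant to total sequencing depth
because depths are fraction-normalized.

**Chromosome fractions.** Per-chromosome z statistics use the *autosomal*
binned total as denominator. With a total-reads denominator, the chrY
signal of a male pregnancy (which moves with $f$) would shift every
autosomal fraction by several panel SDs and guarantee false calls; the
autosomal denominator isolates autosomal dosage from fetal sex.
`chromFractions()` still offers the all-binned denominator, under which
fractions sum to one.

# Aneuploidy calling: two statistics and a consensus

Two independent statistics are computed per autosome:

* the **Stouffer z**, $Z = \sum_b z_b / \sqrt{n}$ over the chromosome's
  non-blacklisted bins — sensitive to a coherent shift spread over many
  bins;
* the **fraction z**, the whole-chromosome read fraction z-scored against
  the panel — a single aggregate insensitive to bin-level weighting.

A trisomy is reported only when *both* are $\ge +3$, a monosomy only when
both are $\le -3$; a single-method crossing is surfaced as `no_consensus`
for manual review rather than silently resolved, and autosomal monosomies
are annotated "rarely reportable". The $|z| \ge 3$ cutoff is the de facto
NIPT convention. Note its arithmetic consequence: under the null each
autosome crosses with probability $\approx 0.003$, so a cohort of 50
euploid samples screened on 22 autosomes is *expected* to produce one or
two spurious consensus flags; specificity near, but not always exactly,
100% is the statistically attainable behaviour at this scale, and the
acceptance suite checks it against that bound.

At fetal fraction 0.04 and 5M binned fragments — the QC floor — the
expected Stouffer z for the smallest commonly screened trisomic chromosome
is about 8, which is why the declared study conditions reproduce full
sensitivity.

# Fetal sex and sex-chromosome aneuploidies

**chrY read ratio.** The fraction of high-quality reads mapping to chrY is
essentially a mismapping background ($\approx 0.0015$) in female
pregnancies and grows linearly with $f$ in male ones. The decision
threshold is 0.01, with ties called male (females sit *below* the
threshold). At the 4% fetal-fraction QC floor the male statistic is
$\approx 0.0175$, comfortably above it.

**chrY marker genes.** The second, independent method uses the fraction of
chrY reads falling in seven Y-specific single-copy genes (SRY, RPS4Y1,
ZFY, USP9Y, DDX3Y, UTY, EIF1AY), with the pseudoautosomal regions (PAR1/2)
excluded. Genuine Y reads concentrate in Y-specific sequence while
mismaps scatter, so the gene fraction separates the sexes around a default
cutoff of 0.5. Both the gene set and the PAR coordinates (GRCh37) ship as
editable BED files.

**SCA.** Female-signature samples are tested on the chrX fraction z: XXX
at $z_X \ge 3$, X0 at $z_X \le -3$. Male-signature samples are classified
over two coordinates — $z_X$ and the *y-level* (the PAR-excluded
seven-region read fraction) — against the expectations of XY, XXY and XYY:
chrX dosage $1 + f(k_X-2)/2$, y-level background $+\, f\,k_Y\,c_{Y1}$. The
per-Y-copy scale $c_{Y1}$ has no absolute published value; it is a
calibration constant stored in the panel (default 0.4, the simulator's
value; a real deployment calibrates it from adult-male or known-$f$
samples). The classifier takes the karyotype minimizing the squared
standardized distance, declares `indeterminate` when the best and
runner-up distances differ by less than 1, and flags as contradictory a
male-labelled sample whose y-level is indistinguishable from the female
background instead of classifying it.

# Fetal fraction

**chrY scaling (male pregnancies).** $\hat f = (y - c_{female})/(c_{male}
- c_{female})$, clipped to $[0,1]$, where $c_{female}$ is the panel's
female background and $c_{male}$ the statistic expected at $f = 1$. The
estimator is exactly linear between the calibration points.

**Elastic-net regression (either sex).** A penalized linear model from
GC-corrected autosomal bin depths to known fetal fractions. Fetal and
maternal cfDNA differ subtly in their bin-level coverage profile
(chromatin structure, fragment ends), which is what makes a
sequence-only estimator possible; the simulator emulates this as a fixed
per-grid "fetal signature" (relative amplitude SD 0.10, mean zero) —
chosen a priori so that the information content (Cramér–Rao error about
0.5 percentage points at 5M fragments) resembles what published
regression estimators achieve. The default mixing parameter is
ridge-dominant ($\alpha = 0.01$): the signal is dense across thousands of
bins with individually tiny coefficients, so strong L1 selection discards
most of it, while retaining a small L1 term still zeroes uninformative
bins. No pretrained weights ship with the package; site calibration on
samples of known fetal fraction is required, and the weighted-rank
variant of sequence-based estimation is out of scope. The QC gate receives
the chrY estimate for male calls and the regression estimate otherwise.

# CNV segmentation

Per-bin z-scores of each chromosome are segmented by a recursive
*interval* scan (circular-binary-segmentation style): the sub-interval
whose mean differs most from the rest of the current segment is scored as
$T = (\bar z_{in} - \bar z_{out})/\sqrt{1/n_{in} + 1/n_{out}}$ and
accepted when $|T| \ge 5$, recursing into the pieces. An interval
statistic, rather than a single-boundary split, is essential: a focal
3-bin event inside a 240-bin chromosome moves any single-boundary mean
difference by only ~1% of its magnitude and would never be found. The
split threshold 5 controls the familywise null rate over the ~$n^2/2$
correlated intervals per chromosome (null maximum ~3.5--4). Segments are
contiguous and exhaustive over informative bins; two bins cannot split.

Calls then require size $\ge 1$ Mb and $|Z_{segment}| \ge 3$; sign gives
duplication versus deletion. Each call is annotated with the expected
single-copy fetal magnitude $\pm\log_2(1 \pm f/2)$ ($\approx +0.070 /
-0.074$ at $f = 0.1$), and segments with $|\overline{\log_2}| \in [0.58,
1]$ — the scale of a maternal heterozygous CNV, which the whole cfDNA pool
carries — are annotated "possibly maternal"; fetal-versus-maternal
deconvolution is deliberately not attempted. In the full pipeline a
chromosome that yields a single segment is not reported as a CNV: whole-
chromosome dosage is the aneuploidy callers' domain.

**Problem sizes for CNV-mode experiments.** Boundary-exact recovery of a
3 Mb event requires per-bin signal well above bin noise. The package's CNV
recovery experiments therefore run in targeted per-chromosome mode: the
affected chromosome alone is simulated and analyzed at the stated binned
depth (chr2 at 1 Mb bins and 10M fragments; chr13 at 100 kb bins and 20M
fragments), where the per-bin z of a 5% dosage shift is ~9 and the
recovered boundaries are exact. On a whole-genome grid at the same totals
the same event sits near the detection threshold ($T \approx 4.8$) and
boundary bins become intrinsically ambiguous — a fair picture of why
clinical CNV mode needs depth concentrated at finer resolution.

# The simulator and what passing tests mean

`simulateCounts()` draws bin counts negative-binomially around
$E_b \propto w_b \, d(k_b, f)\, g(gc_b)\,(1 + f s_b)$, with usability
weights $w_b$, optional linear GC bias $g$, and the fetal signature $s_b$;
chrY receives a per-sample mismap background draw
($\mathcal{N}(0.0015, 0.0005)$, truncated at 0) plus $f\,k_Y\,c_{Y1}$
concentrated in the marker-gene bins. Counts use variance
$(1+\phi)\,\mu$ with $\phi = 0.02$ (NB size $\mu/\phi$; Poisson at
$\phi = 0$) — i.e. $\phi$ is the *fractional excess variance over
Poisson*, a constant variance-inflation factor of the kind left after GC
correction in shallow WGS. Under this model the declared study conditions
(4% fetal fraction, 5M fragments) give trisomy z-scores near 8 and full
sensitivity; a quadratic-in-$\mu$ overdispersion of the same nominal value
would instead imply 14% bin-level noise and no usable signal at these
depths, which is incompatible with the performance this class of pipeline
demonstrably achieves.

The simulator reproduces the statistical structure the callers assume —
and only that. It does not model fragment-size distributions or end
motifs, sequencing error, mappability structure, batch effects, maternal
CNVs or mosaicism (confined placental mosaicism is a known source of
real-world discordance). Passing recovery tests therefore demonstrate
internal correctness and calibration of the statistics, not clinical
performance; the two reported sub-chromosomal events (a 3 Mb duplication
and a 2.4 Mb deletion) are simulated at declared loci (chr2:100--103 Mb
and chr13:50--52.4 Mb) because only their sizes and chromosomes are
published.

A deliberate side effect of simulating focal deletions on a
single-chromosome grid is a slight coherent rise of all flanking bins
(the denominator shrinks by the deleted mass), which can push long flank
segments just past $|Z| = 3$; callers downstream of whole-genome grids do
not see this because the denominator there is the autosomal total.

# Defaults at a glance

| Parameter | Default | Meaning |
|---|---|---|
| bin size | 1 Mb (aneuploidy), 100 kb (CNV) | profile resolution |
| MAPQ cutoff | 30 | "high-quality" read definition |
| read filter | length ≥ 35 bp, mean Q ≥ 20, dedup | whole-read QC, no trimming |
| QC gate | ≥ 1.5M reads, ff ≥ 4% | below this, calls are suppressed |
| z threshold | 3 (both methods, consensus) | aneuploidy / SCA cutoff |
| sex threshold | 0.01 (chrY ratio, ties male); 0.5 (gene method) | fetal sex |
| split threshold | 5 | CNV segmentation acceptance |
| CNV call | ≥ 1 Mb and \|Z\| ≥ 3 | reportable segment |
| lowess span | 0.3 | GC trend smoothing |
| blacklist | >50% N, >10% zero-inflated, SD = 0 | excluded bins |
| dispersion φ | 0.02 | simulator excess variance |
| mismap background | 0.0015 ± 0.0005 | female chrY fraction |
| $c_{Y1}$ | 0.4 | chrY statistic per Y copy at f = 1 |
| enet α | 0.01 | ff regression penalty mix |

The read-quality rule is interpreted as *mean* per-read Phred (reads kept
or dropped whole, deterministically) rather than any trimming schedule,
and duplicate reads are defined by exact sequence identity at the FASTQ
stage (single-end data), with position-level BAM dedup additionally
available in counting.

# Known limitations

* Panel z-scores use plain per-bin mean/SD rather than within-sample
  reference-bin selection or PCA denoising; on real data with mappability
  and batch structure that transparency costs some power.
* The chrY statistics' absolute scale ($c_{Y1}$, the 0.01 threshold's
  generative separation) is calibrated, not derived; a real deployment
  must fit it to platform data.
* Specificity at $|z| \ge 3$ over all 22 autosomes is bounded by Gaussian
  tails (see above); a production screen would restrict reporting to the
  clinically screened trisomies or raise the threshold.
* Fetal vs maternal CNV origin is annotated heuristically, never
  deconvolved; mosaicism and vanishing-twin signals are out of scope.
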