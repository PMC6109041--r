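---
title: "eladkit: models, parameters and design choices"
author: "eladkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{eladkit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(eladkit))
```

## The analysis

Lamin B1 is classically mapped to gene-poor, heterochromatic
lamina-associated domains (cLADs). ChIP-seq on a euchromatin-enriched
chromatin fraction instead reveals lamin B1 bound across active, gene-rich,
C/G-rich regions. Clusters of such lamin B1-positive sites form euchromatin
lamin B1-associated domains (eLADs) of roughly a third of a megabase that
are dynamic across conditions — for example over a TGF-β-induced
epithelial-to-mesenchymal transition (EMT) time course — and that sit in the
active (A) Hi-C compartment, with lamin B1 accumulating at TAD borders as
border strength grows.

eladkit implements that whole analysis as composable, tested pieces:

1. **Site calling** (`callSites`): per-bin one-sided Poisson test of ChIP
   counts against a scaled IgG control, BH-corrected, merged into peaks.
2. **eLAD segmentation** (`callELads`): single-linkage gap merging of peaks
   into domains with a minimum site count.
3. **Gene-centric summaries**: peak location classes, TSS metaprofiles,
   expression strata, target genes, GC content.
4. **Hi-C architecture** (`balanceMatrix`, `compartmentPC1`,
   `insulationScore`, `callBorders`, `matchBorders`,
   `borderPeakOccupancy`): A/B compartments, compartment changes, and
   insulation-based TAD borders with strength and conservation.
5. **Integration statistics** (`featureLandmarkLogOdds`,
   `borderEnrichmentPvalue`, `timepointDynamics`, `deTargetOverlap`,
   `frapNormalize`).
6. **A synthetic-data module** that plants every structure the pipeline is
   supposed to find, so each stage can be scored against a known truth.

## The statistical models

### Site calling

For bin $i$ the ChIP count $x_i$ is tested against
$\lambda_i = \max(s\,c_i,\; b_i,\; 1)$, where $c_i$ is the control count,
$s$ the ChIP/control library-size ratio, and $b_i$ a rolling-mean local
background of the scaled control (25 bins). The p-value is the exact Poisson
upper tail $P(X \ge x_i \mid \lambda_i)$, corrected across bins by
Benjamini–Hochberg; adjacent significant bins merge into peaks and peaks
must reach a mean fold enrichment of `minFold` (default 2). The Poisson null
was chosen over a negative binomial deliberately: it makes the null
analytically checkable, and the generator uses the same noise family so the
caller's type-I behaviour can be verified exactly (an overdispersion
multiplier exists in the generator but is off by default). With the control
track identically zero, the caller falls back to the global ChIP mean with a
warning.

### eLAD segmentation

Peaks whose gap is at most `maxGap` (default 100 kb) chain into clusters;
clusters with at least `minSites` peaks (default 3) become domains spanning
first-peak start to last-peak end. The span is peak-bounded rather than
gap-padded, which keeps coverage estimates conservative. Both parameters are
exposed because no published values exist for them; the defaults were chosen
once so that default synthetic runs produce domains near the 0.34-Mb mean
size the analysis targets. Clustering runs on called peaks by default; a raw
GRanges of intervals (for instance from a control-subtracted signal) is
accepted as an alternative entry point.

### Compartments

The contact matrix is balanced by iterative correction (masking bins whose
marginal is below 2% of the mean marginal), converted to observed/expected
by diagonal distance, correlated column-wise, and the leading eigenvector of
the correlation matrix is PC1. Sign is arbitrary for an eigenvector, so the
profile is oriented against a covariate — gene density by default — such
that positive PC1 ("A") is the gene-dense, active state; negating either the
eigenvector or the covariate therefore cannot silently swap the labels. Bin
changes between two profiles require a PC1 sign flip, optionally with a
minimum |PC1| in both conditions (`minAbsPc1`, default 0, since no published
threshold exists).

### TAD borders

Insulation at bin $i$ is the mean balanced contact in the square pairing the
`window` bins upstream with the `window` bins downstream (default 5 bins,
i.e. 200 kb at 40-kb resolution), log2-normalized by the chromosome-wide
mean. Borders are local insulation minima with topographic prominence at
least `prominenceMin` (default 0.5 log2 units, chosen to sit between the
prominence of planted boundaries, which exceeds 1 at default contrast, and
the Poisson-noise minima, which stay below 0.3). Strength rescales
prominence to 10 at the strongest border of the chromosome, a normalized
0–10 scale; because that normalization is per chromosome and per condition,
cross-condition comparisons (for example "borders deepen over the time
course") should use the raw prominence, exposed as `borderProminence`.
Border conservation clusters borders across conditions by single linkage at
±`tol` bins (default 2): a cluster containing a border from every condition
is conserved, and the conserved fraction divides by the number of clusters
(the union of distinct borders). Empty squares (a fully insulating join) are
floored about 20 log2 units below the mean instead of dropped, so a perfect
two-block matrix still yields a finite, deep minimum at the join.

### Contingency tests and dynamics

Feature-by-landmark tables are built on the landmark's bin grid with
any-overlap feature presence (a minimum-fraction mode exists). The log odds
ratio is natural-log; the Haldane–Anscombe ½ correction is applied only when
a zero cell would make the ratio undefined, so exact values are preserved
whenever they exist. The two-sided p-value is computed by direct
hypergeometric enumeration (`fisherExactP`), and the test suite cross-checks
it against `stats::fisher.test` to 1e-10 relative — the enumeration is the
implementation, the base-R test only the oracle. Border enrichment of a peak
set is a one-sided binomial tail with success probability equal to the
border fraction of the genome (borders = border bin ±1 bin), with a
length-preserving uniform permutation test as an alternative. Target-gene
dynamics across conditions are exact set algebra (all Venn regions;
maintained = full intersection; changed = union minus intersection), with
percentages reported rounded to integers alongside exact fractions. The
FRAP normalization is the standard double-ratio
$\frac{(ROI_b - ROI_{bg})/(ROI_{nb} - ROI_{bg})}
      {(pbROI_b - pbROI_{bg})/(pbROI_{nb} - pbROI_{bg})}$,
vectorized over frames; it is scale-invariant by construction.

## What the generator emulates

`simulateGenome` builds a coordinate frame with three kinds of territory:
cLAD blocks (~1 Mb, gene-poor, default 20% of the genome), planted eLAD
slots (mean 0.34 Mb, gene-rich), and background euchromatin. Genes are
placed with weights 8 : 1 : 0.1 (slots : euchromatin : cLADs), with
log-normal body lengths and random strands. Slot sizes are gamma-distributed
(shape 8) and rescaled so their realized mean equals the configured mean
exactly — the generator's size contract holds at every seed, not only in
expectation. The default frame is a single 20-Mb chromosome, which keeps a
full three-condition run around ten seconds on one core while leaving room
for ~18 slots plus cLADs; multi-chromosome configurations are supported.

Three conditions share a core of domains sized by the retention fraction
(default 0.28, echoing the ~28% of target genes maintained across the EMT
time course) and draw the rest from a common pool, so planted sets overlap
partially and the dynamics accounting has a known answer.

`simulateChipTracks` models a planted domain as a dense cluster of bound
sites: a fraction `siteFraction` (default 0.9) of the domain's bins carries
the bound rate and the rest stays at background, with the rates arranged so
the domain-wide mean enrichment is exactly the configured fold. This
punctate structure is what makes gap merging meaningful downstream — with a
uniform block of enrichment every domain would collapse into a single
contiguous peak and a minimum site count of 3 could never be met. A
TSS-proximal bump (default 1.5×, ±1 kb) at lamin-positive genes reproduces
the coupling between expression and lamin B1 at promoters; setting
`tssBump = 1` and `enrichment = 1` gives an exact chip-equals-control null
for calibration experiments. Counts are Poisson and both tracks scale to the
configured depth.

`simulateHic` multiplies a power-law distance decay `(1+d)^-1` by a
same-compartment factor (default 1.5; cross-label pairs are damped by its
inverse) and a within-TAD factor (default 2.5), then Poisson-samples a
symmetric matrix. Each matrix carries the structure defined at its own truth
grid — the compartment checkerboard at 100 kb, TAD blocks at 40 kb —
mirroring the resolution split of the analysis itself; blending both at 40
kb would create insulation dips at compartment transitions that are not
planted boundaries. `noise = FALSE` returns the expected matrix, the
noise-free limit in which compartment recovery is exact.

What the generator does **not** emulate: mappability and GC bias (a
mappability multiplier exists but defaults to flat), fragment-length
effects, replicate structure, overdispersed counts (off by default),
trans-chromosomal contacts, and any coupling between eLADs and TAD borders
— border enrichment of lamin B1 is exercised through an explicit placement
probability (`simulatePeakSet`) rather than through the ChIP generator.
Passing recovery tests on these simulations therefore shows the estimators
are correct under their stated noise model, not that real libraries satisfy
that model.

## Numerical choices

- Balancing converges when unmasked row sums agree to 1e-8 relative;
  non-convergence within 500 iterations is an error reporting the residual.
- Bins with marginal below 2% of the mean marginal (including all-zero
  rows) are masked and excluded from every downstream statistic; masked
  bins cannot become borders and carry NA PC1.
- Expression strata: silent is FPKM < 0.5 (configurable; no published
  threshold exists), the rest split into tertiles with ties broken by gene
  id and remainders assigned to the upper strata.
- Peak location classes use the peak midpoint, with precedence proximal >
  distal > intragenic > intergenic; upstream of a minus-strand gene means
  coordinates greater than its TSS.
- All files on disk are 0-based half-open (BED convention); in memory the
  package uses GRanges (1-based closed) like the rest of the Bioconductor
  stack, and the readers/writers in one place do the conversion.
- Sub-seeds for the per-condition simulations are derived arithmetically
  from the top-level seed and a stage tag, keeping every value below
  2^31 - 1.

## Problem sizes

The test suite and the acceptance script run the default study: one 20-Mb
chromosome, 600 genes, 12 planted domains per condition across three
conditions, ChIP depth 1e6 at enrichment 4 on 1-kb bins, Hi-C at 100 kb
(200 bins) and 40 kb (500 bins), and 20 null seeds for the FDR calibration.
These sizes make every planted structure comfortably detectable while a
full pipeline run stays near ten seconds on a single core.

## Worked example

```{r example, eval = FALSE}
library(eladkit)
sim <- simulateGenome(seed = 1)
tracks <- simulateChipTracks(sim$genome, sim$truth, "untreated", seed = 2)
sites <- callSites(tracks$chip, tracks$control, condition = "untreated")
elads <- callELads(sites)
domainSummary(elads, sim$genome)
intervalOverlapStats(domains(elads), plantedDomains(sim$truth, "untreated"))
report <- runPipeline(defaultPipelineConfig(seed = 1), outdir = "elad_run")
```

## Known limitations

- The site caller's Poisson null understates variance on overdispersed real
  libraries; rerun calibrations with the generator's overdispersion enabled
  before trusting nominal FDRs on such data.
- Border strength is a per-chromosome relative scale; use
  `borderProminence` for any comparison across conditions or chromosomes.
- `runPipeline` drives the simulated-input study end to end; analyses of
  external files compose the module functions and the readers directly.
- Compartment calling assumes a single dominant eigenvector; chromosomes
  whose leading eigenvector tracks something other than A/B (short arms,
  translocations) need manual inspection of the orientation correlation,
  which the profile records.
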