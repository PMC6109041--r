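# eladkit

Lamin B1 is best known for tethering gene-poor heterochromatin to the
nuclear lamina in constitutive lamina-associated domains (cLADs). ChIP-seq
on a euchromatin-enriched chromatin fraction tells a second story: lamin B1
also binds active, gene-rich, C/G-rich chromatin, where clusters of lamin
B1-positive sites form **euchromatin lamin B1-associated domains (eLADs)**
of roughly 0.3 Mb. These domains are dynamic — across a TGF-β-induced
epithelial-to-mesenchymal transition, most target genes gain or lose lamin
B1 — and they tie into 3D genome architecture: eLADs sit in the active (A)
Hi-C compartment and lamin B1 accumulates at TAD borders as border strength
increases.

eladkit is an R package for that analysis, aimed at epigenomics
bioinformaticians who have binned ChIP/control tracks, expression tables and
intra-chromosomal Hi-C matrices and want the domain calls and architecture
statistics with every step testable:

- **Site calling** — per-bin one-sided Poisson test of ChIP counts against
  the scaled IgG control, `p(x_i) = P(X >= x_i | lambda_i)` with
  `lambda_i = max(s*c_i, local background, 1)`, Benjamini–Hochberg across
  bins, adjacent significant bins merged, minimum fold enforced.
- **eLAD segmentation** — single-linkage gap merging of sites (gap <=
  `maxGap`, default 100 kb; >= `minSites` sites, default 3), domain span
  peak-bounded; summaries (count, mean size, genome coverage) and base-pair
  exact overlap/Jaccard statistics.
- **Gene-centric views** — peak location classes (proximal/distal/
  intragenic/intergenic, strand-aware), TSS metaprofiles in RPM, target
  genes by TSS-window overlap, silent/low/medium/high expression strata, GC
  content of site sequences.
- **Hi-C architecture** — ICE balancing, A/B compartments as the leading
  eigenvector of the observed/expected correlation matrix oriented by gene
  density, per-bin compartment-change classes, insulation-score TAD borders
  with 0–10 normalized strength, border conservation across conditions,
  border lamin occupancy.
- **Integration statistics** — feature x landmark 2x2 log odds with a
  two-sided Fisher exact p computed by hypergeometric enumeration,
  binomial/permutation border-enrichment tests, exact Venn dynamics of
  target-gene sets, FRAP recovery normalization.
- **A synthetic-data module** — genomes with planted cLADs, eLADs,
  compartments, TAD boundaries, lamin-coupled expression and DE sets across
  three partially overlapping conditions, so every stage can be scored
  against a known truth with no downloads.

## Worked example

```r
library(eladkit)
sim    <- simulateGenome(seed = 1)            # genome + planted truth
tracks <- simulateChipTracks(sim$genome, sim$truth, "untreated", seed = 2)
sites  <- callSites(tracks$chip, tracks$control, condition = "untreated")
elads  <- callELads(sites)
sites
#> PeakSet [untreated]: 410 peaks, 3.80 Mb total
elads
#> ELadSet [untreated]: 12 domains, mean size 0.35 Mb
domainSummary(elads, sim$genome)
#>  nDomains  meanSize  coverage
#> 1.200e+01 3.540e+05 2.124e-01
intervalOverlapStats(domains(elads), plantedDomains(sim$truth, "untreated"))$jaccard
#> [1] 0.9971
```

410 significant lamin B1+ sites cluster into 12 domains averaging 0.35 Mb
(21% of the 20-Mb chromosome), and the called domains agree with the planted
ones at base-pair Jaccard 0.997. `runPipeline(defaultPipelineConfig(seed = 1),
outdir = "elad_run")` runs the full study — sites, domains, expression
strata, compartments, borders, contingency tests, dynamics — and writes BED/
bedGraph/TSV outputs plus a machine-readable `report.json`.

## Package layout

- `R/` — S4 classes (`GenomeModel`, `SignalTrack`, `PeakSet`, `ELadSet`,
  `ContactMatrix`, `CompartmentProfile`, `TadPartition`,
  `ContingencyResult`, `DynamicsSummary`, `SyntheticTruth`) with validity
  checks and accessors, plus the module functions.
- `tests/testthat/` — unit and property tests per module, with brute-force
  oracles for clustering, overlap, matching and the exact tests.
- `vignettes/eladkit-methods.Rmd` — the models, parameter choices and what
  the simulations do and do not demonstrate.
- `scripts/acceptance.R` — see above.
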