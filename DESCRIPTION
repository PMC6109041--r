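Package: eladkit
Title: Euchromatin Lamin B1 Domain Analysis from ChIP-seq, Expression and Hi-C
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls lamin B1-positive sites from binned ChIP-seq signal against
    an IgG control with a per-bin Poisson test, segments them into euchromatin
    lamin B1-associated domains (eLADs) by gap merging, and relates the domains
    to gene expression strata, chromatin accessibility and Hi-C architecture:
    A/B compartment eigenvectors, insulation-based TAD borders with normalized
    strength, border conservation and lamin occupancy, and feature-by-landmark
    log-odds contingency tests. A synthetic-data module generates genomes,
    signal tracks, expression tables and contact matrices with planted ground
    truth so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Epigenetics, ChIPSeq, HiC, Coverage, PeakDetection
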