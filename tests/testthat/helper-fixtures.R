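# Shared fixture builders; everything is generated in code at test time.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
})

# A bare single-chromosome genome with explicit genes (start, end, strand).
fixtureGenome <- function(len = 1e6, geneTable = NULL, cladTable = NULL,
                          chrom = "chr1") {
    cl <- setNames(len, chrom)
    genes <- NULL
    if (!is.null(geneTable)) {
        genes <- GRanges(chrom,
            IRanges(start = geneTable$start, end = geneTable$end),
            strand = geneTable$strand)
    }
    clads <- NULL
    if (!is.null(cladTable))
        clads <- GRanges(chrom,
            IRanges(start = cladTable$start, end = cladTable$end))
    GenomeModel(cl, genes = genes, clads = clads)
}

.fixtureGR <- function(starts, ends, len, chrom) {
    gr <- if (length(starts) == 0) GRanges()
          else GRanges(chrom, IRanges(start = starts, end = ends))
    GenomeInfoDb::seqlevels(gr) <- chrom
    GenomeInfoDb::seqlengths(gr) <- len
    sort(gr)
}

# A PeakSet from explicit 1-based closed intervals.
fixturePeaks <- function(starts, ends, len = 1e6, chrom = "chr1",
                         condition = "test") {
    gr <- .fixtureGR(starts, ends, len, chrom)
    mcols(gr)$score <- rep(1, length(gr))
    mcols(gr)$fold <- rep(2, length(gr))
    new("PeakSet", condition = condition, granges = gr)
}

fixtureELads <- function(starts, ends, siteCounts = NULL, len = 1e6,
                         chrom = "chr1", condition = "test") {
    gr <- .fixtureGR(starts, ends, len, chrom)
    mcols(gr)$siteCount <- if (is.null(siteCounts)) rep(1, length(gr))
                           else siteCounts
    new("ELadSet", condition = condition, granges = gr, minSites = 1)
}

fixtureContactMatrix <- function(m, resolution = 1e4, chrom = "chr1",
                                 balanced = FALSE, mask = NULL) {
    if (is.null(mask)) mask <- rep(FALSE, nrow(m))
    new("ContactMatrix", chrom = chrom, resolution = resolution,
        matrix = m, mask = mask, balanced = balanced)
}

fixtureProfile <- function(pc1, resolution = 1e5, chrom = "chr1") {
    labels <- ifelse(is.na(pc1), NA_character_, ifelse(pc1 > 0, "A", "B"))
    new("CompartmentProfile", chrom = chrom, resolution = resolution,
        pc1 = pc1, labels = labels, orientationCor = 1)
}

fixturePartition <- function(borders, nBins, resolution = 4e4,
                             chrom = "chr1", strength = NULL) {
    borders <- as.integer(sort(borders))
    if (is.null(strength))
        strength <- rep(10, length(borders))
    ins <- rep(0, nBins)
    ins[borders] <- -1
    new("TadPartition", chrom = chrom, resolution = resolution,
        insulation = ins, borders = borders, strength = strength,
        prominence = strength / 10, window = 5L)
}

# Default-condition simulation shared by several test files (cached so the
# suite pays for it once).
.simCache <- new.env()
defaultSim <- function(seed = 1) {
    key <- paste0("sim", seed)
    if (is.null(.simCache[[key]]))
        .simCache[[key]] <- simulateGenome(seed = seed)
    .simCache[[key]]
}
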