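#' Two-sided Fisher's exact test by hypergeometric enumeration
#'
#' Enumerates all 2x2 tables with the observed margins and sums the
#' probabilities of tables no more likely than the observed one (with the
#' conventional `1 + 1e-7` tie tolerance). Deliberately implemented from the
#' hypergeometric mass directly so the p-value is exact and auditable.
#'
#' @param a,b,c,d Cell counts: rows feature +/-, columns in/out landmark.
#' @return Two-sided exact p-value in (0, 1].
#' @export
fisherExactP <- function(a, b, c, d) {
    stopifnot(all(c(a, b, c, d) >= 0))
    m <- a + b        # feature-positive bins
    nn <- c + d       # feature-negative bins
    k <- a + c        # landmark bins
    support <- max(0, k - nn):min(k, m)
    probs <- dhyper(support, m, nn, k)
    pObs <- dhyper(a, m, nn, k)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Natural-log odds ratio; Haldane-Anscombe 1/2 correction only when a zero
# cell makes the uncorrected ratio undefined.
.logOdds <- function(a, b, c, d) {
    corrected <- any(c(a, b, c, d) == 0)
    if (corrected) {
        a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    }
    list(logOdds = log((a * d) / (b * c)), corrected = corrected)
}

#' Feature x landmark contingency log-odds with Fisher's exact test
#'
#' Bins the genome at the landmark's resolution, marks each unmasked bin as
#' feature-positive by any-overlap (or by a minimum covered fraction), crosses
#' that with landmark membership and reports the natural-log odds ratio with
#' a two-sided Fisher exact p-value.
#'
#' @param featureIntervals GRanges of the feature (e.g. eLADs, lamin B1+
#'   sites, cLADs).
#' @param landmarkBins Integer bin indices (1-based) belonging to the
#'   landmark (e.g. A-compartment bins, border bins).
#' @param chromLength Chromosome length in bp.
#' @param chrom Chromosome name.
#' @param resolution Bin size of the landmark grid in bp.
#' @param maskedBins Optional integer bin indices excluded from the table.
#' @param minFraction Minimum fraction of a bin covered by the feature to
#'   count as present (default 0 = any overlap).
#' @param feature,landmark Names recorded in the result.
#' @return A [ContingencyResult].
#' @export
featureLandmarkLogOdds <- function(featureIntervals, landmarkBins,
                                   chromLength, chrom, resolution,
                                   maskedBins = integer(0), minFraction = 0,
                                   feature = "feature", landmark = "landmark") {
    n <- as.integer(ceiling(chromLength / resolution))
    evalBins <- setdiff(seq_len(n), maskedBins)
    landmarkBins <- intersect(landmarkBins, evalBins)
    if (length(landmarkBins) == 0 || length(landmarkBins) == length(evalBins))
        stop("landmark set or its complement is empty; odds undefined")
    present <- logical(n)
    fi <- featureIntervals[
        as.character(GenomeInfoDb::seqnames(featureIntervals)) == chrom]
    if (length(fi) > 0) {
        if (minFraction <= 0) {
            present <- .binOverlapIndicator(n, resolution, fi, chrom)
        } else {
            covVec <- as.numeric(IRanges::coverage(
                IRanges::ranges(GenomicRanges::reduce(fi)),
                width = n * resolution))
            frac <- vapply(seq_len(n), function(i)
                mean(covVec[((i - 1) * resolution + 1):(i * resolution)]),
                numeric(1))
            present <- frac >= minFraction
        }
    }
    inLm <- evalBins %in% landmarkBins
    pres <- present[evalBins]
    a <- sum(pres & inLm); b <- sum(pres & !inLm)
    c_ <- sum(!pres & inLm); d <- sum(!pres & !inLm)
    lo <- .logOdds(a, b, c_, d)
    new("ContingencyResult", feature = feature, landmark = landmark,
        counts = matrix(c(a, c_, b, d), 2, 2,
                        dimnames = list(c("feature+", "feature-"),
                                        c("in", "out"))),
        logOdds = lo$logOdds, pValue = fisherExactP(a, b, c_, d),
        corrected = lo$corrected)
}

#' Contingency test from explicit 2x2 counts
#'
#' @param a,b,c,d Cell counts (rows feature +/-, columns in/out landmark).
#' @param feature,landmark Names recorded in the result.
#' @return A [ContingencyResult].
#' @export
contingencyTest <- function(a, b, c, d, feature = "feature",
                            landmark = "landmark") {
    lo <- .logOdds(a, b, c, d)
    new("ContingencyResult", feature = feature, landmark = landmark,
        counts = matrix(c(a, c, b, d), 2, 2,
                        dimnames = list(c("feature+", "feature-"),
                                        c("in", "out"))),
        logOdds = lo$logOdds, pValue = fisherExactP(a, b, c, d),
        corrected = lo$corrected)
}

#' Enrichment of peaks at TAD borders
#'
#' Binomial mode: the number of peaks intersecting a border interval is
#' compared with a Binomial(n = peaks, p = border fraction of the genome)
#' null, one-sided upper tail. Permutation mode: peaks are placed uniformly
#' at random preserving their lengths and the tail probability is
#' `(1 + #{perm >= obs}) / (1 + N)`.
#'
#' @param peakset A [PeakSet].
#' @param partition A [TadPartition].
#' @param genome A [GenomeModel].
#' @param method `"binomial"` (default) or `"permutation"`.
#' @param span Border half-span in bins (default 1).
#' @param nPermutations Permutations for the permutation mode (default 1e4).
#' @param seed Seed for the permutation mode.
#' @return List with `pValue`, `fold` (observed / expected peaks in borders),
#'   `observed`, `expected` and `borderFraction`.
#' @export
borderEnrichmentPvalue <- function(peakset, partition, genome,
                                   method = c("binomial", "permutation"),
                                   span = 1, nPermutations = 1e4, seed = 1) {
    method <- match.arg(method)
    stopifnot(is(peakset, "PeakSet"), is(partition, "TadPartition"),
              is(genome, "GenomeModel"))
    cl <- chromLengths(genome)
    L <- cl[[partition@chrom]]
    iv <- GenomicRanges::reduce(borderIntervals(partition, L, span))
    borderBp <- sum(as.numeric(BiocGenerics::width(iv)))
    p0 <- borderBp / sum(cl)
    gr <- peaks(peakset)
    nPeaks <- length(gr)
    if (nPeaks == 0)
        return(list(pValue = 1, fold = 0, observed = 0, expected = 0,
                    borderFraction = p0))
    obs <- sum(suppressWarnings(IRanges::overlapsAny(gr, iv)))
    expected <- nPeaks * p0
    if (method == "binomial") {
        p <- pbinom(obs - 1, nPeaks, p0, lower.tail = FALSE)
    } else {
        widths <- BiocGenerics::width(gr)
        p <- .withSeed(seed, {
            chroms <- names(cl)
            hits <- vapply(seq_len(nPermutations), function(k) {
                ci <- sample.int(length(cl), nPeaks, replace = TRUE, prob = cl)
                st <- floor(runif(nPeaks, 1, unname(cl[ci]) - widths + 1))
                rg <- .gr(chroms[ci], st, st + widths - 1, cl)
                sum(suppressWarnings(IRanges::overlapsAny(rg, iv)))
            }, numeric(1))
            (1 + sum(hits >= obs)) / (1 + nPermutations)
        })
    }
    list(pValue = p, fold = if (expected > 0) obs / expected else NA_real_,
         observed = obs, expected = expected, borderFraction = p0)
}

#' Set dynamics of lamin B1 target genes across conditions
#'
#' Exact set algebra over the per-condition target-gene sets: all disjoint
#' Venn-region counts, the maintained genes (present in every condition), and
#' the changed genes (union minus intersection). Percentages are reported
#' rounded to the nearest integer; exact fractions are kept in the object.
#'
#' @param targetSets Named list (2 or 3 conditions) of gene-id vectors.
#' @return A [DynamicsSummary].
#' @export
timepointDynamics <- function(targetSets) {
    if (length(targetSets) < 2) stop("need at least two target sets")
    if (length(targetSets) > 3)
        stop("venn accounting supports two or three conditions")
    sets <- lapply(targetSets, unique)
    un <- unique(unlist(sets))
    memb <- vapply(sets, function(s) un %in% s, logical(length(un)))
    if (length(un) == 1) memb <- matrix(memb, nrow = 1)
    key <- apply(memb, 1, function(r) paste(as.integer(r), collapse = ""))
    grid <- as.matrix(expand.grid(rep(list(0:1), length(sets))))
    grid <- grid[rowSums(grid) > 0, , drop = FALSE]
    allKeys <- apply(grid, 1, paste, collapse = "")
    venn <- setNames(numeric(length(allKeys)), sort(allKeys))
    tb <- table(key)
    venn[names(tb)] <- as.numeric(tb)
    inter <- sum(rowSums(memb) == length(sets))
    unionSize <- length(un)
    new("DynamicsSummary",
        conditions = names(sets),
        sets = sets,
        vennCounts = venn,
        maintained = inter,
        changed = unionSize - inter,
        maintainedFraction = if (unionSize > 0) inter / unionSize else 0,
        changedFraction = if (unionSize > 0) (unionSize - inter) / unionSize
                          else 0)
}

#' Overlap between DE genes and lamin B1 targets
#'
#' @param deGenes Character vector of differentially expressed gene ids.
#' @param targets Character vector of lamin B1 target gene ids.
#' @return List with `overlap` (count), `pctTargetsDE` (percentage of targets
#'   that are DE, rounded; exact value in `fracTargetsDE`), `pctDETargets`
#'   (percentage of DE genes that are targets), the exact fractions, and
#'   `emptyTargets` flag (percentages of an empty target set are reported as
#'   0 with the flag raised).
#' @export
deTargetOverlap <- function(deGenes, targets) {
    deGenes <- unique(deGenes); targets <- unique(targets)
    ov <- length(intersect(deGenes, targets))
    emptyTargets <- length(targets) == 0
    fracT <- if (emptyTargets) 0 else ov / length(targets)
    fracD <- if (length(deGenes) == 0) 0 else ov / length(deGenes)
    list(overlap = ov,
         pctTargetsDE = round(100 * fracT),
         pctDETargets = round(100 * fracD),
         fracTargetsDE = fracT,
         fracDETargets = fracD,
         emptyTargets = emptyTargets)
}

#' FRAP recovery normalization
#'
#' Normalizes a bleached region-of-interest intensity by background and
#' non-bleached references, relative to the same ratio before bleaching:
#' `[(ROIb - ROIbg)/(ROInb - ROIbg)] / [(pbROIb - pbROIbg)/(pbROInb -
#' pbROIbg)]`. Vectorized over frames, so a whole recovery time series can be
#' normalized in one call.
#'
#' @param roiB,roiBg,roiNb Post-bleach intensities of the bleached,
#'   background and non-bleached ROIs.
#' @param pbRoiB,pbRoiBg,pbRoiNb The same three ROIs before bleaching.
#' @return Normalized recovery value(s); 1 when post-bleach equals pre-bleach
#'   and 0 at full bleach with no recovery.
#' @export
frapNormalize <- function(roiB, roiBg, roiNb, pbRoiB, pbRoiBg, pbRoiNb) {
    if (any(roiNb <= roiBg))
        stop("non-bleached ROI must exceed background (post-bleach frame)")
    if (any(pbRoiNb <= pbRoiBg))
        stop("non-bleached ROI must exceed background (pre-bleach frame)")
    if (any(pbRoiB == pbRoiBg))
        stop("pre-bleach bleached ROI equals background; ratio undefined")
    ((roiB - roiBg) / (roiNb - roiBg)) /
        ((pbRoiB - pbRoiBg) / (pbRoiNb - pbRoiBg))
}
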