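#' Balance a contact matrix by iterative correction
#'
#' ICE-style iterative proportional fitting: low-coverage bins -- those whose
#' marginal falls below `maskFraction` of the mean marginal (including
#' all-zero rows) -- are masked, then the matrix is repeatedly divided by the
#' outer product of its normalized unmasked row sums until those row sums
#' agree with their mean to within `tol` (relative). Symmetry is preserved
#' exactly.
#'
#' @param cm A [ContactMatrix] of raw counts.
#' @param tol Relative row-sum tolerance (default 1e-8).
#' @param maxIter Iteration cap; non-convergence is an error reporting the
#'   residual.
#' @param maskFraction Mask bins whose marginal is below this fraction of the
#'   mean marginal (default 0.02).
#' @return A balanced [ContactMatrix] with the mask applied (masked rows and
#'   columns zeroed).
#' @export
balanceMatrix <- function(cm, tol = 1e-8, maxIter = 500, maskFraction = 0.02) {
    stopifnot(is(cm, "ContactMatrix"))
    m <- cm@matrix
    n <- nrow(m)
    marg <- rowSums(m)
    mask <- cm@mask | marg == 0
    if (any(!mask))
        mask <- mask | marg < maskFraction * mean(marg[!mask])
    if (sum(!mask) < 2) stop("fewer than two unmasked bins after filtering")
    w <- m
    w[mask, ] <- 0
    w[, mask] <- 0
    resid <- Inf
    for (it in seq_len(maxIter)) {
        s <- rowSums(w)
        sm <- s / mean(s[!mask])
        resid <- max(abs(sm[!mask] - 1))
        if (resid <= tol) break
        sm[mask | sm == 0] <- 1
        w <- w / outer(sm, sm)
    }
    if (resid > tol)
        stop(sprintf("balancing did not converge in %d iterations (residual %.3g)",
                     maxIter, resid))
    w <- (w + t(w)) / 2  # guard against floating-point asymmetry
    new("ContactMatrix", chrom = cm@chrom, resolution = cm@resolution,
        matrix = w, mask = mask, balanced = TRUE)
}

#' A/B compartment PC1 from a balanced contact matrix
#'
#' Standard construction: observed/expected by diagonal distance (expected =
#' mean contact at each separation over unmasked pairs), Pearson correlation
#' matrix across bins, leading eigenvector = PC1. The eigenvector sign is
#' flipped if its correlation with the orientation covariate (for instance
#' gene density) is negative, so that label "A" (PC1 > 0) is the gene-dense /
#' active state. Masked bins get NA PC1 and no label.
#'
#' @param cm A balanced [ContactMatrix].
#' @param orientationCovariate Per-bin numeric covariate (e.g. gene density),
#'   same grid as the matrix.
#' @return A [CompartmentProfile].
#' @seealso [geneDensityCovariate()] to build the default covariate.
#' @export
compartmentPC1 <- function(cm, orientationCovariate) {
    stopifnot(is(cm, "ContactMatrix"))
    if (!cm@balanced)
        stop("matrix must be balanced first (see balanceMatrix)")
    n <- nrow(cm@matrix)
    if (length(orientationCovariate) != n)
        stop("orientation covariate must have one value per bin")
    mask <- cm@mask
    if (sum(!mask) < 10) stop("need at least 10 unmasked bins")
    idx <- which(!mask)
    m <- cm@matrix[idx, idx]
    k <- length(idx)
    d <- abs(outer(seq_len(k), seq_len(k), "-"))
    # distances in original bin units so masking does not distort the decay
    d0 <- abs(outer(idx, idx, "-"))
    expByDist <- vapply(0:(n - 1), function(dd) {
        v <- m[d0 == dd]
        if (length(v) > 0) mean(v) else NA_real_
    }, numeric(1))
    expMat <- matrix(expByDist[d0 + 1], k, k)
    oe <- ifelse(expMat > 0, m / expMat, 0)
    if (all(abs(oe - mean(oe)) < 1e-12))
        stop("degenerate observed/expected matrix")
    cc <- suppressWarnings(cor(oe))
    cc[!is.finite(cc)] <- 0
    eig <- eigen(cc, symmetric = TRUE)
    v <- eig$vectors[, 1]
    cov <- orientationCovariate[idx]
    r <- suppressWarnings(cor(v, cov))
    if (is.na(r)) r <- 0
    if (r < 0) v <- -v
    pc1 <- rep(NA_real_, n)
    pc1[idx] <- v
    labels <- rep(NA_character_, n)
    labels[idx] <- ifelse(v > 0, "A", "B")
    new("CompartmentProfile", chrom = cm@chrom, resolution = cm@resolution,
        pc1 = pc1, labels = labels, orientationCor = abs(r))
}

#' Per-bin gene density on a bin grid
#'
#' Counts TSSs per bin; the default orientation covariate for
#' [compartmentPC1()].
#'
#' @param genome A [GenomeModel].
#' @param chrom Chromosome.
#' @param resolution Bin size in bp.
#' @return Numeric vector of TSS counts per bin.
#' @export
geneDensityCovariate <- function(genome, chrom, resolution) {
    stopifnot(is(genome, "GenomeModel"))
    L <- chromLengths(genome)[[chrom]]
    n <- as.integer(ceiling(L / resolution))
    g <- genes(genome)
    g <- g[as.character(GenomeInfoDb::seqnames(g)) == chrom]
    dens <- numeric(n)
    if (length(g) > 0) {
        b <- floor((S4Vectors::mcols(g)$tss - 1) / resolution) + 1
        tb <- table(b)
        dens[as.integer(names(tb))] <- as.numeric(tb)
    }
    dens
}

#' Classify per-bin compartment changes between two profiles
#'
#' A bin changes compartment when its PC1 sign flips and both |PC1| values
#' are at least `minAbsPc1`; bins masked in either profile are `masked`.
#'
#' @param p1,p2 [CompartmentProfile]s on the same grid and chromosome.
#' @param minAbsPc1 Minimum |PC1| in both profiles for a change call
#'   (default 0).
#' @return List with `labels` (per-bin factor stable/AtoB/BtoA/masked) and
#'   `counts` (named numeric: AtoB, BtoA).
#' @export
classifyBinChanges <- function(p1, p2, minAbsPc1 = 0) {
    stopifnot(is(p1, "CompartmentProfile"), is(p2, "CompartmentProfile"))
    if (p1@chrom != p2@chrom || p1@resolution != p2@resolution ||
        length(p1@pc1) != length(p2@pc1))
        stop("profiles must be on the same grid and chromosome")
    a <- p1@pc1; b <- p2@pc1
    lab <- rep("stable", length(a))
    lab[is.na(a) | is.na(b)] <- "masked"
    ok <- !is.na(a) & !is.na(b)
    chg <- ok & sign(a) != sign(b) & abs(a) >= minAbsPc1 & abs(b) >= minAbsPc1
    lab[chg & a > 0] <- "AtoB"
    lab[chg & a < 0] <- "BtoA"
    lab <- factor(lab, levels = c("stable", "AtoB", "BtoA", "masked"))
    list(labels = lab,
         counts = c(AtoB = sum(lab == "AtoB"), BtoA = sum(lab == "BtoA")))
}

#' Insulation score of a contact matrix
#'
#' For each bin i, the mean balanced contact in the `window` x `window` square
#' pairing the `window` bins upstream with the `window` bins downstream of i,
#' log2-normalized by the chromosome-wide mean square score. Bins within
#' `window` of a chromosome edge, and masked bins, get NA.
#'
#' @param cm A (preferably balanced) [ContactMatrix].
#' @param window Window half-size in bins (default 5).
#' @return Numeric per-bin insulation vector (log2 scale).
#' @export
insulationScore <- function(cm, window = 5) {
    stopifnot(is(cm, "ContactMatrix"))
    .assertScalarNumber(window, "window", 1)
    m <- cm@matrix
    n <- nrow(m)
    mask <- cm@mask
    raw <- rep(NA_real_, n)
    for (i in seq_len(n)) {
        if (i <= window || i > n - window || mask[i]) next
        up <- (i - window):(i - 1)
        dn <- (i + 1):(i + window)
        sq <- m[up, dn, drop = FALSE]
        okU <- !mask[up]; okD <- !mask[dn]
        sq <- sq[okU, okD, drop = FALSE]
        if (length(sq) == 0) next
        raw[i] <- mean(sq)
    }
    mu <- mean(raw, na.rm = TRUE)
    if (!is.finite(mu) || mu <= 0) return(raw)
    # floor zero squares ~20 log2 units below the mean so a fully insulated
    # boundary stays a finite, deep minimum
    ifelse(is.na(raw), NA_real_, log2(pmax(raw, mu * 2^-20) / mu))
}

#' Call TAD borders from an insulation vector
#'
#' Borders are local minima of the insulation score with topographic
#' prominence at least `prominenceMin` (log2 units); strength is prominence normalized to
#' 10 at the strongest border of the chromosome, echoing a 0-10 normalized
#' border-strength scale. NA stretches (edges, masked bins) never produce
#' borders.
#'
#' @param cm A [ContactMatrix] (used for the grid and insulation), or skip it
#'   by passing `insulationVector` directly.
#' @param window Insulation window in bins (default 5).
#' @param prominenceMin Minimum prominence in log2 units (default 0.5).
#' @param insulationVector Optional precomputed insulation vector.
#' @return A [TadPartition].
#' @export
callBorders <- function(cm, window = 5, prominenceMin = 0.5,
                        insulationVector = NULL) {
    stopifnot(is(cm, "ContactMatrix"))
    ins <- if (is.null(insulationVector)) insulationScore(cm, window)
           else insulationVector
    prom <- .minimaProminence(ins)
    keep <- which(!is.na(prom) & prom >= prominenceMin)
    strength <- numeric(0)
    if (length(keep) > 0) {
        maxProm <- max(prom[keep])
        strength <- 10 * prom[keep] / maxProm
    }
    new("TadPartition", chrom = cm@chrom, resolution = cm@resolution,
        insulation = ins, borders = as.integer(keep), strength = strength,
        prominence = unname(prom[keep]), window = as.integer(window))
}

# Topographic prominence of every local minimum of x (NA elsewhere). For a
# minimum at i with value v, walk left and right to the nearest strictly
# lower value (or the end of the contiguous non-NA segment), track the
# maximum passed on each side; prominence = min(leftMax, rightMax) - v.
.minimaProminence <- function(x) {
    n <- length(x)
    prom <- rep(NA_real_, n)
    for (i in seq_len(n)) {
        if (i == 1 || i == n || is.na(x[i]) ||
            is.na(x[i - 1]) || is.na(x[i + 1])) next
        # interior local minimum; a plateau contributes its leftmost bin
        if (!(x[i] < x[i - 1] && x[i] <= x[i + 1])) next
        leftMax <- -Inf
        j <- i - 1
        while (j >= 1 && !is.na(x[j]) && x[j] >= x[i]) {
            leftMax <- max(leftMax, x[j]); j <- j - 1
        }
        rightMax <- -Inf
        j <- i + 1
        while (j <= n && !is.na(x[j]) && x[j] >= x[i]) {
            rightMax <- max(rightMax, x[j]); j <- j + 1
        }
        prom[i] <- min(leftMax, rightMax) - x[i]
    }
    prom
}

#' Match borders across conditions and compute the conserved fraction
#'
#' Borders from all conditions are clustered by single linkage at `tol` bins;
#' a cluster is conserved when it contains a border from every condition
#' (i.e., every other condition has a border within the tolerance; greedy
#' nearest matching with ties to the lower index). The conserved fraction is
#' conserved clusters over all clusters (the union of borders).
#'
#' @param partitions Named list of [TadPartition]s at the same resolution.
#' @param tol Matching tolerance in bins (default 2).
#' @return List with `conservedFraction`, `conserved` (representative bin per
#'   conserved cluster: the lowest member index), `clusters` (data.frame of
#'   bin, condition, cluster id) and per-condition logical `isConserved`.
#' @export
matchBorders <- function(partitions, tol = 2) {
    stopifnot(length(partitions) >= 2)
    res <- unique(vapply(partitions, function(p) p@resolution, numeric(1)))
    if (length(res) != 1) stop("partitions must share a resolution")
    tab <- do.call(rbind, lapply(names(partitions), function(nm)
        data.frame(bin = partitions[[nm]]@borders, condition = nm)))
    if (is.null(tab) || nrow(tab) == 0)
        return(list(conservedFraction = NA_real_, conserved = integer(0),
                    clusters = data.frame(), isConserved = list()))
    tab <- tab[order(tab$bin, tab$condition), , drop = FALSE]
    cl <- cumsum(c(TRUE, diff(tab$bin) > tol))
    tab$cluster <- cl
    nCond <- length(partitions)
    conservedCl <- vapply(split(tab$condition, tab$cluster),
                          function(cc) length(unique(cc)) == nCond, logical(1))
    conserved <- vapply(split(tab$bin, tab$cluster), min, numeric(1))
    conserved <- as.integer(conserved[conservedCl])
    isConserved <- lapply(names(partitions), function(nm) {
        b <- partitions[[nm]]@borders
        cls <- tab$cluster[match(paste(b, nm), paste(tab$bin, tab$condition))]
        unname(conservedCl[as.character(cls)])
    })
    names(isConserved) <- names(partitions)
    list(conservedFraction = sum(conservedCl) / length(conservedCl),
         conserved = conserved,
         clusters = tab,
         isConserved = isConserved)
}

#' Border intervals of a TAD partition
#'
#' The genomic interval of a border is its bin extended by `span` bins on
#' each side.
#'
#' @param partition A [TadPartition].
#' @param chromLength Chromosome length in bp (to clip the last interval).
#' @param span Bins added on each side of the border bin (default 1).
#' @return GRanges of border intervals.
#' @export
borderIntervals <- function(partition, chromLength, span = 1) {
    stopifnot(is(partition, "TadPartition"))
    b <- partition@borders
    res <- partition@resolution
    cl <- setNames(chromLength, partition@chrom)
    if (length(b) == 0) return(.emptyGR(cl))
    start <- pmax(1, (b - 1 - span) * res + 1)
    end <- pmin(chromLength, (b + span) * res)
    .gr(partition@chrom, start, end, cl)
}

#' Count lamin B1 peaks in each TAD border
#'
#' Counts the peaks intersecting each border interval (border bin +/- `span`
#' bins) and reports the per-border counts plus a histogram over
#' {0, 1, 2, >=3}, the categories of the border-occupancy pie charts.
#'
#' @param partition A [TadPartition].
#' @param peakset A [PeakSet].
#' @param chromLength Chromosome length in bp.
#' @param span Border half-span in bins (default 1).
#' @return List with `perBorder` (integer counts) and `histogram` (named
#'   numeric over "0","1","2",">=3").
#' @export
borderPeakOccupancy <- function(partition, peakset, chromLength, span = 1) {
    stopifnot(is(partition, "TadPartition"), is(peakset, "PeakSet"))
    iv <- borderIntervals(partition, chromLength, span)
    counts <- if (length(iv) == 0) integer(0)
        else suppressWarnings(IRanges::countOverlaps(iv, peaks(peakset)))
    bins <- cut(counts, breaks = c(-0.5, 0.5, 1.5, 2.5, Inf),
                labels = c("0", "1", "2", ">=3"))
    hist <- table(bins)
    list(perBorder = as.integer(counts),
         histogram = setNames(as.numeric(hist), names(hist)))
}
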