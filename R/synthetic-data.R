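#' Simulate a genome with planted eLADs, cLADs and genes
#'
#' Builds a [GenomeModel] and the matching [SyntheticTruth] for a small study
#' with several conditions. Constitutive LAD (cLAD) blocks are gene-poor;
#' planted eLAD slots are gene-rich euchromatin domains whose mean size
#' defaults to 0.34 Mb. Conditions share a core of domains (the retention
#' fraction) and draw the rest from a common pool, so per-condition planted
#' sets overlap partially. The truth also carries per-bin A/B compartment
#' labels (cLAD-majority bins are B, with a few label flips per condition),
#' TAD boundary bins, per-gene lamin status (TSS inside a planted domain) and
#' DE gene sets coupled to lamin status.
#'
#' @param chromLengths Named numeric vector of chromosome lengths in bp.
#' @param nGenes Total number of genes to place.
#' @param cladFraction Fraction of the genome covered by cLADs.
#' @param nDomains Number of planted eLADs per condition.
#' @param meanDomainSize Mean planted domain size in bp.
#' @param conditions Condition labels in temporal order.
#' @param retention Fraction of each condition's domains shared by all
#'   conditions (the "maintained" core).
#' @param minDomainGap Minimum gap between placed blocks in bp; keep it above
#'   the downstream `maxGap` so distinct planted domains are not merged.
#' @param meanCladSize Mean cLAD size in bp.
#' @param compartmentResolution,tadResolution Truth bin sizes in bp.
#' @param flipRuns,flipRunLength Number and length (bins) of compartment-label
#'   runs flipped between consecutive conditions.
#' @param borderRetention Probability that each base TAD boundary is present
#'   in a given condition.
#' @param deRatePositive,deRateNegative Per-gene probability of membership in
#'   the condition's DE set, by lamin status.
#' @param seed Integer seed; identical inputs give identical outputs.
#' @return A list with elements `genome` ([GenomeModel]) and `truth`
#'   ([SyntheticTruth]).
#' @examples
#' sim <- simulateGenome(seed = 1)
#' sim$genome
#' sim$truth
#' @export
simulateGenome <- function(chromLengths = c(chr1 = 2e7),
                           nGenes = 600,
                           cladFraction = 0.2,
                           nDomains = 12,
                           meanDomainSize = 3.4e5,
                           conditions = c("untreated", "tgfb_8h", "tgfb_24h"),
                           retention = 0.28,
                           minDomainGap = 1.5e5,
                           meanCladSize = 1e6,
                           compartmentResolution = 1e5,
                           tadResolution = 4e4,
                           flipRuns = 2,
                           flipRunLength = 4,
                           borderRetention = 0.85,
                           deRatePositive = 0.42,
                           deRateNegative = 0.15,
                           seed = 1) {
    stopifnot(length(chromLengths) >= 1, all(chromLengths > 0))
    .assertScalarNumber(cladFraction, "cladFraction", 0, 1)
    .assertScalarNumber(retention, "retention", 0, 1)
    .assertScalarNumber(nDomains, "nDomains", 0)
    .assertScalarNumber(nGenes, "nGenes", 0)
    if (is.null(names(chromLengths)))
        stop("chromLengths must be named")

    .withSeed(seed, {
        core <- round(retention * nDomains)
        extra <- nDomains - core
        nSlots <- if (nDomains > 0) core + ceiling(1.6 * extra) else 0

        # distribute slots/cLADs across chromosomes by length (largest remainder)
        share <- chromLengths / sum(chromLengths)
        slotPerChrom <- .apportion(nSlots, share)
        placed <- lapply(seq_along(chromLengths), function(ci) {
            chr <- names(chromLengths)[ci]
            L <- chromLengths[[ci]]
            nS <- slotPerChrom[ci]
            nC <- round(cladFraction * L / meanCladSize)
            if (nS * meanDomainSize / L + cladFraction > 1)
                stop("cLAD fraction plus planted eLAD fraction exceeds 1 on ", chr)
            slotSz <- if (nS > 0) {
                s <- pmin(pmax(rgamma(nS, shape = 8, rate = 8 / meanDomainSize),
                               0.4 * meanDomainSize), 2.2 * meanDomainSize)
                # anchor the realized mean at the configured mean so the
                # generator's size contract holds at every seed
                s * meanDomainSize / mean(s)
            } else numeric(0)
            cladSz <- if (nC > 0)
                pmin(pmax(rgamma(nC, shape = 4, rate = 4 / meanCladSize),
                          0.3 * meanCladSize), 2.5 * meanCladSize)
            else numeric(0)
            sizes <- round(c(slotSz, cladSz))
            types <- c(rep("slot", nS), rep("clad", nC))
            iv <- .packIntervals(sizes, L, minDomainGap, chr)
            iv$type <- types[iv$item]
            iv
        })
        slots <- do.call(rbind, lapply(placed, function(p) p[p$type == "slot", ]))
        cladTab <- do.call(rbind, lapply(placed, function(p) p[p$type == "clad", ]))

        cladsGR <- if (!is.null(cladTab) && nrow(cladTab) > 0)
            sort(.gr(cladTab$chrom, cladTab$start, cladTab$end, chromLengths))
        else .emptyGR(chromLengths)

        # condition assignment: a shared core plus per-condition draws from
        # the remaining pool
        plantedELads <- list()
        if (nSlots > 0) {
            slotIdx <- seq_len(nrow(slots))
            coreIdx <- if (core > 0) sample(slotIdx, core) else integer(0)
            poolIdx <- setdiff(slotIdx, coreIdx)
            for (cond in conditions) {
                pick <- c(coreIdx,
                          if (extra > 0) sample(poolIdx, min(extra, length(poolIdx)))
                          else integer(0))
                sl <- slots[sort(pick), , drop = FALSE]
                plantedELads[[cond]] <-
                    sort(.gr(sl$chrom, sl$start, sl$end, chromLengths))
            }
        } else {
            for (cond in conditions) plantedELads[[cond]] <- .emptyGR(chromLengths)
        }

        genesGR <- .placeGenes(nGenes, chromLengths, slots, cladsGR)

        geneLaminStatus <- lapply(plantedELads, function(el) {
            if (length(genesGR) == 0)
                return(setNames(logical(0), character(0)))
            tss <- .gr(as.character(GenomeInfoDb::seqnames(genesGR)),
                       S4Vectors::mcols(genesGR)$tss,
                       S4Vectors::mcols(genesGR)$tss, chromLengths)
            setNames(IRanges::countOverlaps(tss, el) > 0,
                     S4Vectors::mcols(genesGR)$gene_id)
        })

        deGenes <- lapply(geneLaminStatus, function(st) {
            if (length(st) == 0) return(character(0))
            p <- ifelse(st, deRatePositive, deRateNegative)
            names(st)[runif(length(st)) < p]
        })

        compartmentLabels <- .plantCompartments(chromLengths, cladsGR,
            conditions, compartmentResolution, flipRuns, flipRunLength)
        tadBoundaries <- .plantBoundaries(chromLengths, conditions,
            tadResolution, borderRetention)

        genome <- new("GenomeModel", chromLengths = chromLengths,
                      genes = genesGR, clads = cladsGR)
        truth <- new("SyntheticTruth",
            conditions = conditions,
            plantedELads = plantedELads,
            compartmentLabels = compartmentLabels,
            tadBoundaries = tadBoundaries,
            geneLaminStatus = geneLaminStatus,
            deGenes = deGenes,
            compartmentResolution = compartmentResolution,
            tadResolution = tadResolution)
        list(genome = genome, truth = truth)
    })
}

# Integer apportionment by largest remainder.
.apportion <- function(n, share) {
    raw <- n * share
    base <- floor(raw)
    rem <- n - sum(base)
    if (rem > 0) {
        extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
    }
    as.integer(base)
}

# Place blocks of given sizes on [1, L] without overlap, keeping at least
# minGap bp between blocks, in random order with random slack distribution.
# Errors when the blocks cannot fit.
.packIntervals <- function(sizes, L, minGap, chrom) {
    n <- length(sizes)
    if (n == 0)
        return(data.frame(item = integer(0), chrom = character(0),
                          start = numeric(0), end = numeric(0)))
    need <- sum(sizes) + (n + 1) * minGap
    if (need > L)
        stop(sprintf(
            "cannot fit %d blocks (%.2f Mb + gaps) on %s (%.2f Mb)",
            n, sum(sizes) / 1e6, chrom, L / 1e6))
    ord <- sample.int(n)
    slack <- L - need
    w <- rexp(n + 1)
    gapExtra <- floor(slack * w / sum(w))
    pos <- minGap + gapExtra[1] + 1
    start <- numeric(n); end <- numeric(n)
    for (k in seq_len(n)) {
        i <- ord[k]
        start[i] <- pos
        end[i] <- pos + sizes[i] - 1
        pos <- end[i] + 1 + minGap + gapExtra[k + 1]
    }
    data.frame(item = seq_len(n), chrom = chrom, start = start, end = end)
}

# Genes are placed preferentially in the eLAD slot pool (gene-rich), then in
# other euchromatin; cLADs are strongly depleted.
.placeGenes <- function(nGenes, chromLengths, slots, cladsGR,
                        weightSlot = 8, weightEu = 1, weightClad = 0.1) {
    if (nGenes == 0) {
        gr <- .emptyGR(chromLengths)
        S4Vectors::mcols(gr)$gene_id <- character(0)
        S4Vectors::mcols(gr)$tss <- numeric(0)
        return(gr)
    }
    regions <- list()
    for (chr in names(chromLengths)) {
        L <- chromLengths[[chr]]
        slotGR <- if (!is.null(slots) && nrow(slots) > 0) {
            s <- slots[slots$chrom == chr, , drop = FALSE]
            if (nrow(s)) .gr(s$chrom, s$start, s$end, chromLengths)
            else .emptyGR(chromLengths)
        } else .emptyGR(chromLengths)
        cl <- cladsGR[as.character(GenomeInfoDb::seqnames(cladsGR)) == chr]
        occupied <- GenomicRanges::reduce(c(slotGR, cl))
        eu <- GenomicRanges::setdiff(
            .gr(chr, 1, L, chromLengths), occupied)
        addRegion <- function(gr, w) {
            if (length(gr) == 0) return(NULL)
            data.frame(chrom = chr,
                       start = BiocGenerics::start(gr),
                       end = BiocGenerics::end(gr),
                       weight = w * BiocGenerics::width(gr))
        }
        regions[[length(regions) + 1]] <- addRegion(slotGR, weightSlot)
        regions[[length(regions) + 1]] <- addRegion(eu, weightEu)
        regions[[length(regions) + 1]] <- addRegion(cl, weightClad)
    }
    regions <- do.call(rbind, regions)
    ridx <- sample.int(nrow(regions), nGenes, replace = TRUE,
                       prob = regions$weight)
    tss <- floor(regions$start[ridx] +
                 runif(nGenes) * (regions$end[ridx] - regions$start[ridx] + 1))
    chrom <- regions$chrom[ridx]
    len <- round(pmin(pmax(rlnorm(nGenes, log(2e4), 0.6), 2000), 150000))
    strand <- sample(c("+", "-"), nGenes, replace = TRUE)
    L <- chromLengths[chrom]
    start <- ifelse(strand == "+", tss, pmax(1, tss - len + 1))
    end <- ifelse(strand == "+", pmin(L, tss + len - 1), tss)
    gr <- .gr(chrom, start, end, chromLengths, strand = strand)
    gr <- sort(gr, ignore.strand = TRUE)
    S4Vectors::mcols(gr)$gene_id <- sprintf("g%05d", seq_len(nGenes))
    st <- as.character(BiocGenerics::strand(gr))
    S4Vectors::mcols(gr)$tss <- ifelse(st == "+", BiocGenerics::start(gr),
                                       BiocGenerics::end(gr))
    gr
}

# Base A/B labels: B where cLADs dominate a bin; per condition, a few runs of
# bins flip label relative to the previous condition (compartment dynamics).
.plantCompartments <- function(chromLengths, cladsGR, conditions, res,
                               flipRuns, flipRunLength) {
    chr <- names(chromLengths)[1]
    n <- as.integer(ceiling(chromLengths[[1]] / res))
    cov <- numeric(n)
    cl <- cladsGR[as.character(GenomeInfoDb::seqnames(cladsGR)) == chr]
    if (length(cl) > 0) {
        covRle <- IRanges::coverage(IRanges::ranges(cl), width = n * res)
        covVec <- as.numeric(covRle)
        cov <- vapply(seq_len(n), function(i)
            mean(covVec[((i - 1) * res + 1):(i * res)]), numeric(1))
    }
    base <- ifelse(cov >= 0.5, "B", "A")
    out <- list()
    prev <- base
    for (k in seq_along(conditions)) {
        lab <- prev
        if (k > 1 && flipRuns > 0) {
            starts <- sample(seq_len(max(1, n - flipRunLength)), flipRuns)
            for (s in starts) {
                idx <- s:min(n, s + flipRunLength - 1)
                lab[idx] <- ifelse(lab[idx] == "A", "B", "A")
            }
        }
        out[[conditions[k]]] <- lab
        prev <- lab
    }
    out
}

# Base boundary set spaced 15-30 bins apart away from chromosome edges; each
# condition retains each boundary independently.
.plantBoundaries <- function(chromLengths, conditions, res, borderRetention,
                             edge = 8L) {
    n <- as.integer(ceiling(chromLengths[[1]] / res))
    pos <- integer(0)
    cur <- edge
    repeat {
        cur <- cur + sample(15:30, 1)
        if (cur > n - edge) break
        pos <- c(pos, cur)
    }
    out <- list()
    for (cond in conditions) {
        keep <- runif(length(pos)) < borderRetention
        out[[cond]] <- as.integer(pos[keep])
    }
    out
}

#' Simulate ChIP and IgG control coverage tracks
#'
#' Per-bin counts are Poisson. The control rate is uniform (optionally scaled
#' by a mappability track); the ChIP rate is elevated inside the condition's
#' planted eLADs so the domain-wide mean enrichment equals `enrichment`, with
#' an additional TSS-proximal bump at lamin-positive genes. A planted domain
#' is modeled as a dense cluster of bound site bins: a fraction
#' `siteFraction` of its bins carries the (correspondingly higher) bound
#' rate and the rest stays at background, which reproduces the punctate
#' site-within-domain structure that gap merging downstream relies on. Both
#' tracks are scaled so the expected total equals `depth`.
#'
#' @param genome A [GenomeModel].
#' @param truth The matching [SyntheticTruth].
#' @param condition Condition label present in `truth`.
#' @param depth Expected total read count per track. `depth = 0` returns
#'   all-zero tracks with a warning.
#' @param enrichment Mean fold enrichment of the ChIP rate inside planted
#'   eLADs (must be >= 1; 1 gives a chip track distributed exactly like the
#'   control).
#' @param siteFraction Fraction of a planted domain's bins that are bound
#'   sites; the remaining bins stay at background so site runs are separated
#'   by short gaps (default 0.9).
#' @param binSize Bin width in bp.
#' @param tssBump Extra multiplicative bump on ChIP bins within
#'   `tssBumpHalfWidth` of a lamin-positive TSS. Set to 1 for an exact
#'   chip-equals-control null when `enrichment = 1`.
#' @param tssBumpHalfWidth Half-width of the bump window in bp.
#' @param overdispersion Gamma-Poisson overdispersion parameter; 0 (default)
#'   gives pure Poisson counts.
#' @param mappability Optional named list of per-chromosome multipliers on the
#'   bin grid, applied to both tracks.
#' @param seed Integer seed.
#' @return A list with [SignalTrack] elements `chip` and `control`.
#' @export
simulateChipTracks <- function(genome, truth, condition,
                               depth = 1e6, enrichment = 4, binSize = 1000,
                               siteFraction = 0.9,
                               tssBump = 1.5, tssBumpHalfWidth = 1000,
                               overdispersion = 0, mappability = NULL,
                               seed = 1) {
    stopifnot(is(genome, "GenomeModel"), is(truth, "SyntheticTruth"))
    if (!condition %in% truth@conditions)
        stop("unknown condition: ", condition)
    if (enrichment < 1) stop("enrichment must be >= 1")
    .assertScalarNumber(siteFraction, "siteFraction", 0.01, 1)
    .assertScalarNumber(depth, "depth", 0)
    cl <- chromLengths(genome)
    nb <- .nBins(cl, binSize)
    if (depth == 0) {
        warning("depth is 0; returning all-zero tracks")
        zero <- lapply(nb, numeric)
        z <- new("SignalTrack", binSize = binSize, values = zero,
                 librarySize = 0)
        return(list(chip = z, control = z))
    }
    el <- plantedDomains(truth, condition)
    status <- truth@geneLaminStatus[[condition]]
    g <- genes(genome)
    posTss <- g[S4Vectors::mcols(g)$gene_id %in% names(status)[status]]

    .withSeed(seed, {
        chipRate <- list(); ctrlRate <- list()
        for (chr in names(cl)) {
            n <- nb[[chr]]
            r <- rep(1, n)
            inDom <- .binOverlapIndicator(n, binSize, el, chr)
            # bound-site bins at rate 1 + (enrichment-1)/siteFraction, gap
            # bins at background: domain-wide mean is exactly `enrichment`
            isSite <- inDom & runif(n) < siteFraction
            r[isSite] <- 1 + (enrichment - 1) / siteFraction
            if (tssBump != 1 && length(posTss) > 0) {
                tssHere <- posTss[as.character(GenomeInfoDb::seqnames(posTss)) == chr]
                if (length(tssHere) > 0) {
                    tpos <- S4Vectors::mcols(tssHere)$tss
                    bumpGR <- .gr(chr, pmax(1, tpos - tssBumpHalfWidth),
                                  pmin(cl[[chr]], tpos + tssBumpHalfWidth), cl)
                    bump <- .binOverlapIndicator(n, binSize, bumpGR, chr)
                    r[bump] <- r[bump] * tssBump
                }
            }
            m <- rep(1, n)
            if (!is.null(mappability)) {
                m <- mappability[[chr]]
                if (length(m) != n) stop("mappability grid mismatch on ", chr)
            }
            chipRate[[chr]] <- r * m
            ctrlRate[[chr]] <- m
        }
        sample1 <- function(rates) {
            tot <- sum(unlist(rates))
            vals <- lapply(rates, function(r) {
                lam <- r / tot * depth
                if (overdispersion > 0)
                    lam <- lam * rgamma(length(lam), shape = 1 / overdispersion,
                                        scale = overdispersion)
                as.numeric(rpois(length(lam), lam))
            })
            new("SignalTrack", binSize = binSize, values = vals,
                librarySize = sum(unlist(vals)))
        }
        chip <- sample1(chipRate)
        control <- sample1(ctrlRate)
        list(chip = chip, control = control)
    })
}

#' Simulate a gene expression table (FPKM per condition)
#'
#' FPKM values are log-normal with a higher location parameter for
#' lamin-positive genes (status taken from the truth, per condition). A
#' configurable fraction of genes is set to exactly zero ("silent"), drawn
#' preferentially from lamin-negative genes.
#'
#' @param genome A [GenomeModel].
#' @param truth The matching [SyntheticTruth].
#' @param baseMeanLog Location (log scale) for lamin-negative genes.
#' @param sdLog Log-scale standard deviation.
#' @param shift Log-scale location shift for lamin-positive genes; 0 decouples
#'   expression from lamin status.
#' @param silentFraction Fraction of genes set to FPKM 0 per condition.
#' @param seed Integer seed.
#' @return A data.frame with column `gene_id` and one `fpkm_<condition>`
#'   column per condition (the package's ExpressionTable).
#' @export
simulateExpression <- function(genome, truth, baseMeanLog = 1, sdLog = 1,
                               shift = 1.5, silentFraction = 0.15, seed = 1) {
    stopifnot(is(genome, "GenomeModel"), is(truth, "SyntheticTruth"))
    .assertScalarNumber(silentFraction, "silentFraction", 0, 1)
    g <- genes(genome)
    ids <- S4Vectors::mcols(g)$gene_id
    .withSeed(seed, {
        out <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
        for (cond in truth@conditions) {
            status <- truth@geneLaminStatus[[cond]]
            if (!all(ids %in% names(status)))
                stop("gene_lamin_status missing for some genes")
            st <- status[ids]
            fpkm <- rlnorm(length(ids), baseMeanLog + shift * st, sdLog)
            nSilent <- round(silentFraction * length(ids))
            if (nSilent > 0) {
                w <- ifelse(st, 1, 5)
                silent <- sample.int(length(ids), nSilent, prob = w)
                fpkm[silent] <- 0
            }
            out[[paste0("fpkm_", cond)]] <- fpkm
        }
        out
    })
}

#' Simulate an intra-chromosomal Hi-C contact matrix
#'
#' The expected contact between bins i and j is a power-law distance decay
#' times a compartment factor (same-label bins boosted, cross-label damped)
#' times a TAD factor (within-TAD pairs boosted), Poisson-sampled and
#' symmetric by construction. Each matrix carries the structure defined on
#' its own truth grid: the compartment checkerboard is applied at the
#' compartment resolution and the TAD blocks at the TAD resolution, matching
#' the analysis each resolution serves. With `noise = FALSE` the expected
#' matrix itself is returned (the noise-free limit).
#'
#' @param genome A [GenomeModel].
#' @param truth The matching [SyntheticTruth].
#' @param condition Condition label.
#' @param resolution Bin size in bp; must equal the truth's compartment or TAD
#'   resolution, otherwise an error is raised.
#' @param chrom Chromosome to simulate (default: first).
#' @param compartmentFactor Same-label boost f (cross-label pairs get 1/f).
#'   1 disables compartment structure.
#' @param tadFactor Within-TAD boost; 1 disables TAD structure.
#' @param depthScale Expected contact count at distance 0 before structure
#'   factors.
#' @param decayExponent Power-law exponent of the distance decay
#'   `(1+d)^-alpha`.
#' @param noise Poisson-sample the counts (TRUE) or return the expected
#'   matrix (FALSE).
#' @param seed Integer seed.
#' @return A [ContactMatrix] of raw counts (unbalanced, no bins masked).
#' @export
simulateHic <- function(genome, truth, condition, resolution = 1e5,
                        chrom = names(chromLengths(genome))[1],
                        compartmentFactor = 1.5, tadFactor = 2.5,
                        depthScale = 100, decayExponent = 1,
                        noise = TRUE, seed = 1) {
    stopifnot(is(genome, "GenomeModel"), is(truth, "SyntheticTruth"))
    if (!condition %in% truth@conditions)
        stop("unknown condition: ", condition)
    if (resolution <= 0) stop("resolution must be positive")
    if (!resolution %in% c(truth@compartmentResolution, truth@tadResolution))
        stop(sprintf(
            "resolution %d is incompatible with the truth bin grids (%d, %d)",
            as.integer(resolution), as.integer(truth@compartmentResolution),
            as.integer(truth@tadResolution)))
    L <- chromLengths(genome)[[chrom]]
    n <- as.integer(ceiling(L / resolution))
    mid <- (seq_len(n) - 0.5) * resolution

    labSrc <- truth@compartmentLabels[[condition]]
    labIdx <- pmin(floor(mid / truth@compartmentResolution) + 1, length(labSrc))
    lab <- labSrc[labIdx]

    boundBp <- (truth@tadBoundaries[[condition]] - 1) * truth@tadResolution
    block <- findInterval(mid, boundBp)

    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    e <- depthScale * (1 + d)^(-decayExponent)
    if (compartmentFactor != 1 && resolution == truth@compartmentResolution) {
        same <- outer(lab, lab, "==")
        e <- e * ifelse(same, compartmentFactor, 1 / compartmentFactor)
    }
    if (tadFactor != 1 && resolution == truth@tadResolution) {
        sameTad <- outer(block, block, "==")
        e <- e * ifelse(sameTad, tadFactor, 1)
    }
    m <- if (noise) {
        .withSeed(seed, {
            up <- upper.tri(e, diag = TRUE)
            v <- rpois(sum(up), e[up])
            m <- matrix(0, n, n)
            m[up] <- v
            m <- m + t(m)
            diag(m) <- diag(m) / 2
            m
        })
    } else e
    new("ContactMatrix", chrom = chrom, resolution = resolution,
        matrix = m, mask = rep(FALSE, n), balanced = FALSE)
}

#' Simulate a peak set with a controllable at-border placement probability
#'
#' Places `nPeaks` fixed-width peaks on the genome; each peak lands inside a
#' randomly chosen border interval with probability `atBorderProb` and
#' uniformly elsewhere otherwise. Used to exercise the border-enrichment test
#' with a known effect size. Overlapping placements are merged.
#'
#' @param genome A [GenomeModel].
#' @param nPeaks Number of peaks to place.
#' @param borderIntervals GRanges of border intervals.
#' @param atBorderProb Probability that a peak is placed inside a border.
#' @param peakWidth Peak width in bp.
#' @param condition Label for the resulting [PeakSet].
#' @param seed Integer seed.
#' @return A [PeakSet].
#' @export
simulatePeakSet <- function(genome, nPeaks, borderIntervals, atBorderProb,
                            peakWidth = 1000, condition = "synthetic",
                            seed = 1) {
    stopifnot(is(genome, "GenomeModel"))
    .assertScalarNumber(atBorderProb, "atBorderProb", 0, 1)
    cl <- chromLengths(genome)
    .withSeed(seed, {
        chrom <- character(nPeaks); start <- numeric(nPeaks)
        atBorder <- runif(nPeaks) < atBorderProb & length(borderIntervals) > 0
        for (k in seq_len(nPeaks)) {
            if (atBorder[k]) {
                b <- borderIntervals[sample.int(length(borderIntervals), 1)]
                chrom[k] <- as.character(GenomeInfoDb::seqnames(b))
                lo <- BiocGenerics::start(b)
                hi <- max(lo, BiocGenerics::end(b) - peakWidth + 1)
                start[k] <- floor(runif(1, lo, hi + 1))
            } else {
                ci <- sample.int(length(cl), 1, prob = cl)
                chrom[k] <- names(cl)[ci]
                start[k] <- floor(runif(1, 1, cl[[ci]] - peakWidth + 1))
            }
        }
        gr <- .gr(chrom, start, pmin(start + peakWidth - 1, cl[chrom]), cl)
        gr <- GenomicRanges::reduce(sort(gr))
        S4Vectors::mcols(gr)$score <- rep(1, length(gr))
        S4Vectors::mcols(gr)$fold <- rep(1, length(gr))
        new("PeakSet", condition = condition, granges = gr)
    })
}
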