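#' Call lamin B1-positive sites from ChIP vs control tracks
#'
#' Per bin, the ChIP count is tested against a Poisson null whose rate is the
#' largest of (i) the library-size-scaled control count, (ii) the scaled local
#' control background (rolling mean over `localWindow` bins), and (iii) a
#' pseudocount. One-sided upper-tail p-values are Benjamini-Hochberg adjusted
#' across all tested bins; significant adjacent bins are merged into peaks and
#' peaks whose mean fold enrichment over the null rate is below `minFold` are
#' dropped.
#'
#' An all-zero control track triggers a fallback to the global ChIP mean as
#' background, with a warning.
#'
#' @param chip,control [SignalTrack]s on identical bin grids.
#' @param fdr Benjamini-Hochberg threshold (default 0.05).
#' @param minFold Minimum mean fold enrichment per peak (default 2).
#' @param pseudocount Floor on the null rate (default 1).
#' @param localWindow Width in bins of the local-background rolling mean
#'   (default 25 bins).
#' @param condition Label for the resulting [PeakSet].
#' @return A [PeakSet]; `score` is -log10 of the smallest adjusted p in the
#'   peak (capped at 1000 on the -10*log10 BED scale at write time), `fold`
#'   the mean chip/null ratio.
#' @export
callSites <- function(chip, control, fdr = 0.05, minFold = 2,
                      pseudocount = 1, localWindow = 25,
                      condition = "condition1") {
    stopifnot(is(chip, "SignalTrack"), is(control, "SignalTrack"))
    if (chip@binSize != control@binSize ||
        !identical(names(chip@values), names(control@values)) ||
        !identical(lengths(chip@values), lengths(control@values)))
        stop("chip and control tracks must share the same bin grid")
    .assertScalarNumber(fdr, "fdr", 0, 1)

    chromLens <- vapply(chip@values, length, integer(1)) * chip@binSize
    chipLib <- chip@librarySize
    ctrlLib <- control@librarySize
    if (chipLib == 0) {
        return(new("PeakSet", condition = condition,
                   granges = .emptyGR(chromLens)))
    }
    globalFallback <- ctrlLib == 0
    if (globalFallback)
        warning("all-zero control track; falling back to global chip background")
    scale <- if (globalFallback) 1 else chipLib / ctrlLib

    perChrom <- lapply(names(chip@values), function(chr) {
        x <- chip@values[[chr]]
        y <- control@values[[chr]]
        scaledCtrl <- if (globalFallback)
            rep(mean(unlist(chip@values)), length(x)) else y * scale
        localBg <- .rollMean(scaledCtrl, localWindow)
        lambda <- pmax(scaledCtrl, localBg, pseudocount)
        p <- ppois(x - 1, lambda, lower.tail = FALSE)
        data.frame(chrom = chr, bin = seq_along(x), x = x,
                   lambda = lambda, p = p)
    })
    tab <- do.call(rbind, perChrom)
    tab$q <- p.adjust(tab$p, method = "BH")
    sig <- tab[tab$q <= fdr & tab$x > 0, , drop = FALSE]
    if (nrow(sig) == 0)
        return(new("PeakSet", condition = condition,
                   granges = .emptyGR(chromLens)))

    bs <- chip@binSize
    peaksByChrom <- lapply(split(sig, sig$chrom), function(s) {
        s <- s[order(s$bin), , drop = FALSE]
        runStart <- c(TRUE, diff(s$bin) > 1)
        grp <- cumsum(runStart)
        do.call(rbind, lapply(split(s, grp), function(run) {
            data.frame(
                chrom = run$chrom[1],
                start = (run$bin[1] - 1) * bs + 1,
                end = min(run$bin[nrow(run)] * bs,
                          chromLens[[run$chrom[1]]]),
                score = -log10(max(min(run$q), 1e-300)),
                fold = mean(run$x) / mean(run$lambda))
        }))
    })
    pk <- do.call(rbind, peaksByChrom)
    pk <- pk[pk$fold >= minFold, , drop = FALSE]
    if (nrow(pk) == 0)
        return(new("PeakSet", condition = condition,
                   granges = .emptyGR(chromLens)))
    gr <- sort(.gr(pk$chrom, pk$start, pk$end, chromLens,
                   score = pk$score, fold = pk$fold))
    new("PeakSet", condition = condition, granges = gr)
}

# Centered rolling mean with edge truncation.
.rollMean <- function(x, w) {
    n <- length(x)
    if (n == 0 || w <= 1) return(x)
    half <- floor(w / 2)
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - half, 1)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Classify peak locations relative to gene annotation
#'
#' Each peak (by its midpoint) is classified as `proximal` (within 0.5 kb of a
#' TSS), `distal` (0.5-2.5 kb upstream of a TSS, strand-aware: upstream of a
#' minus-strand gene means coordinates greater than its TSS), `intragenic`
#' (inside a gene body) or `intergenic`, with precedence in that order.
#'
#' @param peakset A [PeakSet].
#' @param genome A [GenomeModel] with stranded genes.
#' @return A list with `category` (per-peak factor) and `fractions` (named
#'   numeric summing to 1; NaN-free only when there is at least one peak).
#' @export
annotatePeakLocations <- function(peakset, genome) {
    stopifnot(is(peakset, "PeakSet"), is(genome, "GenomeModel"))
    gr <- peaks(peakset)
    lv <- c("proximal", "distal", "intragenic", "intergenic")
    if (length(gr) == 0)
        return(list(category = factor(character(0), levels = lv),
                    fractions = setNames(rep(NA_real_, 4), lv)))
    cl <- chromLengths(genome)
    midPos <- floor((BiocGenerics::start(gr) + BiocGenerics::end(gr)) / 2)
    mid <- .gr(as.character(GenomeInfoDb::seqnames(gr)), midPos, midPos, cl)
    g <- genes(genome)
    cat <- rep("intergenic", length(gr))
    if (length(g) > 0) {
        tssPos <- S4Vectors::mcols(g)$tss
        chr <- as.character(GenomeInfoDb::seqnames(g))
        st <- as.character(BiocGenerics::strand(g))
        proxGR <- .gr(chr, pmax(1, tssPos - 500), pmin(cl[chr], tssPos + 500), cl)
        distStart <- ifelse(st == "+", tssPos - 2500, tssPos + 501)
        distEnd <- ifelse(st == "+", tssPos - 501, tssPos + 2500)
        distGR <- .gr(chr, pmax(1, distStart), pmin(cl[chr], distEnd), cl)
        body <- .gr(chr, BiocGenerics::start(g), BiocGenerics::end(g), cl)
        cat[IRanges::countOverlaps(mid, body) > 0] <- "intragenic"
        cat[IRanges::countOverlaps(mid, distGR) > 0] <- "distal"
        cat[IRanges::countOverlaps(mid, proxGR) > 0] <- "proximal"
    }
    cat <- factor(cat, levels = lv)
    list(category = cat, fractions = prop.table(table(cat)))
}

#' Lamin B1 target genes: peak overlap with a TSS window
#'
#' A gene is a target iff any peak overlaps `[TSS - window, TSS + window)`.
#'
#' @param peakset A [PeakSet].
#' @param genome A [GenomeModel].
#' @param tssWindow Half-width of the TSS window in bp (default 2000).
#' @return Character vector of target gene ids (deduplicated, sorted).
#' @export
assignTargetGenes <- function(peakset, genome, tssWindow = 2000) {
    stopifnot(is(peakset, "PeakSet"), is(genome, "GenomeModel"))
    .assertScalarNumber(tssWindow, "tssWindow", 1)
    g <- genes(genome)
    gr <- peaks(peakset)
    if (length(gr) == 0 || length(g) == 0) return(character(0))
    cl <- chromLengths(genome)
    tssPos <- S4Vectors::mcols(g)$tss
    chr <- as.character(GenomeInfoDb::seqnames(g))
    win <- .gr(chr, pmax(1, tssPos - tssWindow),
               pmin(cl[chr], tssPos + tssWindow - 1), cl)
    hit <- IRanges::countOverlaps(win, gr) > 0
    sort(unique(S4Vectors::mcols(g)$gene_id[hit]))
}

#' Strand-oriented mean signal profile around TSSs
#'
#' Averages reads-per-million normalized signal over the bins covering
#' `[TSS - flank, TSS + flank)` for the given genes; minus-strand windows are
#' reversed before averaging, so the profile reads 5' to 3'. Windows running
#' off a chromosome end contribute NA positions, which are dropped from the
#' mean.
#'
#' @param track A [SignalTrack]; `flank` must be a multiple of its bin size.
#' @param geneIds Character vector of gene ids (non-empty).
#' @param genome A [GenomeModel].
#' @param flank Half-window in bp (default 2000).
#' @return Numeric vector of length `2 * flank / binSize`: mean RPM per
#'   position, 5' to 3'; positions are bin offsets relative to the TSS.
#' @export
tssMetaprofile <- function(track, geneIds, genome, flank = 2000) {
    stopifnot(is(track, "SignalTrack"), is(genome, "GenomeModel"))
    if (length(geneIds) == 0) stop("gene set is empty")
    bs <- track@binSize
    if (flank %% bs != 0) stop("flank must be a multiple of the bin size")
    g <- genes(genome)
    keep <- S4Vectors::mcols(g)$gene_id %in% geneIds
    if (!any(keep)) stop("none of the gene ids are annotated")
    g <- g[keep]
    nbinsWin <- as.integer(2 * flank / bs)
    lib <- track@librarySize
    rpmScale <- if (lib > 0) 1e6 / lib else 1
    acc <- matrix(NA_real_, nrow = length(g), ncol = nbinsWin)
    fb <- flank / bs
    for (k in seq_along(g)) {
        chr <- as.character(GenomeInfoDb::seqnames(g))[k]
        v <- track@values[[chr]]
        tss <- S4Vectors::mcols(g)$tss[k]
        tssBin <- floor((tss - 1) / bs) + 1
        minus <- as.character(BiocGenerics::strand(g))[k] == "-"
        # oriented so the TSS bin sits at position fb + 1 for either strand
        idx <- if (minus) (tssBin - fb + 1):(tssBin + fb)
               else (tssBin - fb):(tssBin + fb - 1)
        vals <- ifelse(idx >= 1 & idx <= length(v),
                       v[pmax(pmin(idx, length(v)), 1)], NA_real_)
        if (minus) vals <- rev(vals)
        acc[k, ] <- vals * rpmScale
    }
    colMeans(acc, na.rm = TRUE)
}

#' Stratify genes into silent/low/medium/high expression categories
#'
#' Genes with FPKM below `silentThreshold` are silent; the remainder is split
#' into low/medium/high tertiles of FPKM (ties broken by gene-id order; when
#' the non-silent count is not divisible by 3 the extra genes go to the upper
#' strata).
#'
#' @param expr ExpressionTable data.frame (`gene_id` + `fpkm_<condition>`
#'   columns).
#' @param condition Condition whose column to stratify.
#' @param silentThreshold FPKM below which a gene is silent (default 0.5).
#' @return Named factor (levels silent/low/medium/high) over gene ids.
#' @export
stratifyExpression <- function(expr, condition, silentThreshold = 0.5) {
    col <- paste0("fpkm_", condition)
    if (!col %in% colnames(expr))
        stop("no expression column for condition: ", condition)
    fpkm <- expr[[col]]
    ids <- expr$gene_id
    lv <- c("silent", "low", "medium", "high")
    out <- rep("silent", length(ids))
    ns <- which(fpkm >= silentThreshold)
    if (length(ns) > 0) {
        o <- ns[order(fpkm[ns], ids[ns])]
        n <- length(o)
        cuts <- floor(seq(0, n, length.out = 4))
        sizes <- diff(cuts)
        out[o] <- rep(c("low", "medium", "high"), times = sizes)
    }
    setNames(factor(out, levels = lv), ids)
}

#' GC content of peak sequences
#'
#' Computes the GC fraction of each peak and the pooled AT/CG composition of
#' the full peak set. Ambiguous bases (N) are excluded from denominators.
#'
#' @param peakset A [PeakSet].
#' @param sequences A named [Biostrings::DNAStringSet] (one entry per
#'   chromosome) or a path to a FASTA file.
#' @return A list with `gc` (per-peak GC fraction in `[0,1]`) and `pooled`
#'   (named numeric: fractions `AT` and `CG` over all peak bases).
#' @export
peakNucleotideContent <- function(peakset, sequences) {
    stopifnot(is(peakset, "PeakSet"))
    if (is.character(sequences))
        sequences <- Biostrings::readDNAStringSet(sequences)
    gr <- peaks(peakset)
    if (length(gr) == 0)
        return(list(gc = numeric(0),
                    pooled = c(AT = NA_real_, CG = NA_real_)))
    chr <- as.character(GenomeInfoDb::seqnames(gr))
    if (!all(chr %in% names(sequences)))
        stop("sequence missing for chromosome(s): ",
             paste(setdiff(chr, names(sequences)), collapse = ", "))
    if (any(BiocGenerics::end(gr) >
            Biostrings::width(sequences)[match(chr, names(sequences))]))
        stop("peak extends beyond the end of its chromosome sequence")
    seqs <- Biostrings::DNAStringSet(lapply(seq_along(gr), function(k)
        Biostrings::subseq(sequences[[chr[k]]],
                           BiocGenerics::start(gr)[k],
                           BiocGenerics::end(gr)[k])))
    freq <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
    denom <- rowSums(freq)
    gc <- ifelse(denom > 0, (freq[, "C"] + freq[, "G"]) / denom, NA_real_)
    tot <- colSums(freq)
    totalACGT <- sum(tot)
    pooled <- c(AT = unname((tot["A"] + tot["T"]) / totalACGT),
                CG = unname((tot["C"] + tot["G"]) / totalACGT))
    list(gc = gc, pooled = pooled)
}
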