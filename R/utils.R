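# Internal helpers shared across modules.

# GRanges constructor that attaches seqlengths from a chromLengths vector so
# out-of-bounds intervals are caught early.
.gr <- function(chrom, start, end, chromLengths, ...) {
    gr <- GenomicRanges::GRanges(
        seqnames = chrom,
        ranges = IRanges::IRanges(start = start, end = end),
        ...
    )
    GenomeInfoDb::seqlevels(gr) <- names(chromLengths)
    GenomeInfoDb::seqlengths(gr) <- unname(chromLengths)
    gr
}

.emptyGR <- function(chromLengths = numeric(0)) {
    gr <- GenomicRanges::GRanges()
    if (length(chromLengths)) {
        GenomeInfoDb::seqlevels(gr) <- names(chromLengths)
        GenomeInfoDb::seqlengths(gr) <- unname(chromLengths)
    }
    gr
}

# Number of bins per chromosome for a bin size.
.nBins <- function(chromLengths, binSize) {
    setNames(as.integer(ceiling(chromLengths / binSize)), names(chromLengths))
}

# Bin grid as GRanges: bin i covers [(i-1)*binSize+1, min(i*binSize, L)],
# 1-based closed (written as 0-based half-open at I/O time).
.binGrid <- function(chromLengths, binSize) {
    out <- lapply(names(chromLengths), function(chr) {
        L <- chromLengths[[chr]]
        n <- ceiling(L / binSize)
        st <- (seq_len(n) - 1) * binSize + 1
        en <- pmin(seq_len(n) * binSize, L)
        .gr(chr, st, en, chromLengths)
    })
    do.call(c, out)
}

# Per-bin fraction/indicator of overlap with a feature GRanges on one chrom.
.binOverlapIndicator <- function(nBins, binSize, feature, chrom) {
    hit <- logical(nBins)
    if (length(feature) == 0) return(hit)
    feature <- feature[as.character(GenomeInfoDb::seqnames(feature)) == chrom]
    if (length(feature) == 0) return(hit)
    for (k in seq_along(feature)) {
        b1 <- floor((BiocGenerics::start(feature)[k] - 1) / binSize) + 1
        b2 <- floor((BiocGenerics::end(feature)[k] - 1) / binSize) + 1
        hit[b1:min(b2, nBins)] <- TRUE
    }
    hit
}

# Evaluate a thunk under a fixed RNG state, restoring the caller's state.
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
                add = TRUE)
    }
    set.seed(as.integer(seed))
    force(expr)
}

# Derive a distinct sub-seed (< 2^31) from a base seed and a string tag.
.subSeed <- function(seed, tag) {
    h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
    as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lower || x > upper)
        stop(sprintf("`%s` must be a number in [%s, %s]", name, lower, upper),
             call. = FALSE)
    invisible(x)
}
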