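#' Segment lamin B1+ sites into eLADs by gap merging
#'
#' Single-linkage chaining: consecutive peaks on a chromosome whose inter-peak
#' gap is at most `maxGap` belong to one cluster. Clusters with at least
#' `minSites` member peaks become domains spanning the first peak's start to
#' the last peak's end (peak-bounded, not gap-padded); smaller clusters are
#' discarded. Unsorted or overlapping input peaks are normalized (sorted and
#' merged) with a warning.
#'
#' @param peakset A [PeakSet], or a raw GRanges of site intervals (normalized
#'   with a warning when unsorted or overlapping).
#' @param maxGap Maximum inter-peak gap in bp (default 1e5).
#' @param minSites Minimum member peaks per domain (default 3).
#' @return An [ELadSet]; each domain carries its member-site count.
#' @export
callELads <- function(peakset, maxGap = 1e5, minSites = 3) {
    .assertScalarNumber(maxGap, "maxGap", 1)
    .assertScalarNumber(minSites, "minSites", 1)
    cond <- if (is(peakset, "PeakSet")) peakset@condition else "unknown"
    gr <- .asGRanges(peakset)
    if (length(gr) == 0)
        return(new("ELadSet", condition = cond,
                   granges = gr, minSites = minSites))
    if (!S4Vectors::isSorted(gr) || any(IRanges::countOverlaps(gr, gr) > 1)) {
        warning("peak input not sorted/disjoint; normalizing")
        gr <- GenomicRanges::reduce(sort(gr))
    }
    clusters <- GenomicRanges::reduce(gr, min.gapwidth = maxGap + 1)
    siteCount <- IRanges::countOverlaps(clusters, gr)
    keep <- siteCount >= minSites
    dom <- clusters[keep]
    S4Vectors::mcols(dom)$siteCount <- siteCount[keep]
    new("ELadSet", condition = cond, granges = dom, minSites = minSites)
}

#' Domain-level summary of an eLAD set
#'
#' @param elads An [ELadSet].
#' @param genome A [GenomeModel] (denominator for genome coverage).
#' @return Named numeric: `nDomains`, `meanSize` (bp; 0 for an empty set) and
#'   `coverage` (total domain bp over total genome bp).
#' @export
domainSummary <- function(elads, genome) {
    stopifnot(is(elads, "ELadSet"), is(genome, "GenomeModel"))
    gl <- sum(chromLengths(genome))
    if (gl <= 0) stop("genome length must be positive")
    gr <- domains(elads)
    n <- length(gr)
    totalBp <- sum(as.numeric(BiocGenerics::width(gr)))
    c(nDomains = n,
      meanSize = if (n > 0) totalBp / n else 0,
      coverage = totalBp / gl)
}

#' Base-pair overlap statistics between two interval sets
#'
#' Both sets are normalized (sorted, merged) before a base-pair-exact
#' intersection. Reports the fraction of A's bases covered by B, the Jaccard
#' index (intersection over union, in bp) and a per-A-interval overlap flag.
#'
#' @param setA,setB GRanges (or [ELadSet]/[PeakSet], whose intervals are
#'   taken).
#' @param threshold Minimum fraction of an A interval that must intersect B
#'   for its flag to be TRUE. The default 0 means any overlapping base.
#' @return List with `fractionAinB`, `jaccard`, `overlapFlags`.
#' @export
intervalOverlapStats <- function(setA, setB, threshold = 0) {
    a <- GenomicRanges::reduce(sort(.asGRanges(setA)))
    b <- GenomicRanges::reduce(sort(.asGRanges(setB)))
    widthOf <- function(gr) sum(as.numeric(BiocGenerics::width(gr)))
    if (length(a) == 0)
        return(list(fractionAinB = NA_real_,
                    jaccard = if (length(b) == 0) NA_real_ else 0,
                    overlapFlags = logical(0)))
    inter <- suppressWarnings(
        GenomicRanges::intersect(GenomicRanges::granges(a),
                                 GenomicRanges::granges(b),
                                 ignore.strand = TRUE))
    wi <- widthOf(inter); wa <- widthOf(a); wb <- widthOf(b)
    ovPerA <- numeric(length(a))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(a, b))
    if (length(hits) > 0) {
        qi <- S4Vectors::queryHits(hits)
        w <- BiocGenerics::width(IRanges::pintersect(
            IRanges::ranges(a)[qi],
            IRanges::ranges(b)[S4Vectors::subjectHits(hits)]))
        agg <- tapply(w, qi, sum)
        ovPerA[as.integer(names(agg))] <- as.numeric(agg)
    }
    perA <- if (threshold <= 0) ovPerA > 0
            else ovPerA / as.numeric(BiocGenerics::width(a)) >= threshold
    list(fractionAinB = wi / wa,
         jaccard = if (wa + wb - wi > 0) wi / (wa + wb - wi) else NA_real_,
         overlapFlags = perA)
}

.asGRanges <- function(x) {
    if (is(x, "GRanges")) x
    else if (is(x, "ELadSet")) domains(x)
    else if (is(x, "PeakSet")) peaks(x)
    else stop("cannot interpret object as intervals")
}

#' Classify eLADs as maintained, new or lost across ordered conditions
#'
#' A domain of condition t is `maintained` if it overlaps (any base pair by
#' default, or reciprocally at 50% with `mode = "reciprocal50"`) at least one
#' domain of every earlier condition, and `new` otherwise. Symmetrically, a
#' domain is `lost` if some later condition has no overlapping domain.
#'
#' @param eladList Named list of [ELadSet] (or GRanges), in temporal order;
#'   at least two conditions.
#' @param mode `"any"` (default) or `"reciprocal50"`.
#' @return Named list per condition with GRanges elements `maintained`, `new`
#'   and `lost`.
#' @export
compareELadSets <- function(eladList, mode = c("any", "reciprocal50")) {
    mode <- match.arg(mode)
    if (length(eladList) < 2) stop("need at least two conditions")
    sets <- lapply(eladList, .asGRanges)
    overlapsSet <- function(query, subject) {
        if (length(query) == 0) return(logical(0))
        if (length(subject) == 0) return(rep(FALSE, length(query)))
        if (mode == "any")
            return(IRanges::overlapsAny(query, subject))
        hits <- GenomicRanges::findOverlaps(query, subject)
        ok <- rep(FALSE, length(query))
        if (length(hits) > 0) {
            qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
            ov <- BiocGenerics::width(IRanges::pintersect(
                IRanges::ranges(query)[qi], IRanges::ranges(subject)[si]))
            good <- ov / BiocGenerics::width(query)[qi] >= 0.5 &
                    ov / BiocGenerics::width(subject)[si] >= 0.5
            ok[unique(qi[good])] <- TRUE
        }
        ok
    }
    out <- list()
    for (t in seq_along(sets)) {
        gr <- sets[[t]]
        earlier <- if (t > 1) seq_len(t - 1) else integer(0)
        later <- if (t < length(sets)) (t + 1):length(sets) else integer(0)
        inAllEarlier <- rep(TRUE, length(gr))
        for (u in earlier)
            inAllEarlier <- inAllEarlier & overlapsSet(gr, sets[[u]])
        inAllLater <- rep(TRUE, length(gr))
        for (u in later)
            inAllLater <- inAllLater & overlapsSet(gr, sets[[u]])
        out[[names(eladList)[t]]] <- list(
            maintained = gr[inAllEarlier],
            new = gr[!inAllEarlier],
            lost = gr[!inAllLater])
    }
    out
}
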