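#' Construct a GenomeModel
#'
#' @param chromLengths Named numeric vector of chromosome lengths in bp.
#' @param genes GRanges of gene bodies. Needs a `gene_id` metadata column
#'   (generated as g0001... when absent) and strands `+`/`-`; the `tss`
#'   column is derived from the strand (5' end) when absent.
#' @param clads GRanges of cLAD intervals.
#' @return A validated [GenomeModel].
#' @examples
#' gm <- GenomeModel(c(chr1 = 1e6))
#' @export
GenomeModel <- function(chromLengths, genes = NULL, clads = NULL) {
    if (is.null(genes)) {
        genes <- .emptyGR(chromLengths)
        S4Vectors::mcols(genes)$gene_id <- character(0)
        S4Vectors::mcols(genes)$tss <- numeric(0)
    } else {
        GenomeInfoDb::seqlevels(genes) <-
            union(GenomeInfoDb::seqlevels(genes), names(chromLengths))
        GenomeInfoDb::seqlengths(genes) <-
            unname(chromLengths[GenomeInfoDb::seqlevels(genes)])
        if (!"gene_id" %in% colnames(S4Vectors::mcols(genes)))
            S4Vectors::mcols(genes)$gene_id <-
                sprintf("g%04d", seq_along(genes))
        if (!"tss" %in% colnames(S4Vectors::mcols(genes))) {
            st <- as.character(BiocGenerics::strand(genes))
            S4Vectors::mcols(genes)$tss <-
                ifelse(st == "+", BiocGenerics::start(genes),
                       BiocGenerics::end(genes))
        }
    }
    if (is.null(clads)) clads <- .emptyGR(chromLengths)
    else {
        GenomeInfoDb::seqlevels(clads) <-
            union(GenomeInfoDb::seqlevels(clads), names(chromLengths))
        GenomeInfoDb::seqlengths(clads) <-
            unname(chromLengths[GenomeInfoDb::seqlevels(clads)])
    }
    new("GenomeModel", chromLengths = chromLengths, genes = genes,
        clads = clads)
}

#' Construct a SignalTrack
#'
#' @param values Named list of per-chromosome numeric bin vectors, or a
#'   single numeric vector (taken as chromosome "chr1").
#' @param binSize Bin width in bp.
#' @param librarySize Total count; defaults to the sum of the values.
#' @return A validated [SignalTrack].
#' @examples
#' st <- SignalTrack(rpois(100, 5), binSize = 1000)
#' @export
SignalTrack <- function(values, binSize, librarySize = NULL) {
    if (is.numeric(values)) values <- list(chr1 = values)
    if (is.null(librarySize)) librarySize <- sum(unlist(values))
    new("SignalTrack", binSize = binSize, values = values,
        librarySize = librarySize)
}
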