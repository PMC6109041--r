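#' Accessors for eladkit classes
#'
#' Small accessor generics so user code never touches slots directly:
#' `chromLengths`, `genes`, `clads` (GenomeModel); `binSize`, `trackValues`,
#' `librarySize` (SignalTrack); `peaks` (PeakSet); `domains` (ELadSet);
#' `contactMap`, `binMask`, `resolution` (ContactMatrix); `pc1`,
#' `compartmentLabels` (CompartmentProfile); `insulation`, `borders`,
#' `borderStrength` (TadPartition); `plantedDomains`, `conditions`
#' (SyntheticTruth); `oddsRatio`, `pValue` (ContingencyResult).
#'
#' @param x,object An eladkit object (`object` for generics inherited from
#'   BiocGenerics).
#' @param condition For SyntheticTruth accessors, which condition to return.
#' @param ... Passed to methods.
#' @return The slot contents (see each class's documentation).
#' @name accessors
#' @aliases chromLengths genes clads binSize trackValues librarySize peaks
#'   domains contactMap binMask resolution pc1 compartmentLabels insulation
#'   borders borderStrength plantedDomains conditions oddsRatio pValue
NULL

#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))
#' @rdname accessors
#' @export
setMethod("chromLengths", "GenomeModel", function(x) x@chromLengths)

#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname accessors
#' @export
setMethod("genes", "GenomeModel", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("clads", function(x) standardGeneric("clads"))
#' @rdname accessors
#' @export
setMethod("clads", "GenomeModel", function(x) x@clads)

#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @rdname accessors
#' @export
setMethod("binSize", "SignalTrack", function(x) x@binSize)

#' @rdname accessors
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))
#' @rdname accessors
#' @export
setMethod("trackValues", "SignalTrack", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("librarySize", function(x) standardGeneric("librarySize"))
#' @rdname accessors
#' @export
setMethod("librarySize", "SignalTrack", function(x) x@librarySize)

#' @rdname accessors
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))
#' @rdname accessors
#' @export
setMethod("peaks", "PeakSet", function(x) x@granges)

#' @rdname accessors
#' @export
setGeneric("domains", function(x) standardGeneric("domains"))
#' @rdname accessors
#' @export
setMethod("domains", "ELadSet", function(x) x@granges)

#' @rdname accessors
#' @export
setGeneric("contactMap", function(x) standardGeneric("contactMap"))
#' @rdname accessors
#' @export
setMethod("contactMap", "ContactMatrix", function(x) x@matrix)

#' @rdname accessors
#' @export
setGeneric("binMask", function(x) standardGeneric("binMask"))
#' @rdname accessors
#' @export
setMethod("binMask", "ContactMatrix", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("resolution", function(x) standardGeneric("resolution"))
#' @rdname accessors
#' @export
setMethod("resolution", "ContactMatrix", function(x) x@resolution)
#' @rdname accessors
#' @export
setMethod("resolution", "CompartmentProfile", function(x) x@resolution)
#' @rdname accessors
#' @export
setMethod("resolution", "TadPartition", function(x) x@resolution)

#' @rdname accessors
#' @export
setGeneric("pc1", function(x) standardGeneric("pc1"))
#' @rdname accessors
#' @export
setMethod("pc1", "CompartmentProfile", function(x) x@pc1)

#' @rdname accessors
#' @export
setGeneric("compartmentLabels", function(x, condition) standardGeneric("compartmentLabels"))
#' @rdname accessors
#' @export
setMethod("compartmentLabels", "CompartmentProfile",
    function(x, condition) x@labels)
#' @rdname accessors
#' @export
setMethod("compartmentLabels", "SyntheticTruth",
    function(x, condition) x@compartmentLabels[[condition]])

#' @rdname accessors
#' @export
setGeneric("insulation", function(x) standardGeneric("insulation"))
#' @rdname accessors
#' @export
setMethod("insulation", "TadPartition", function(x) x@insulation)

#' @rdname accessors
#' @export
setGeneric("borders", function(x) standardGeneric("borders"))
#' @rdname accessors
#' @export
setMethod("borders", "TadPartition", function(x) x@borders)

#' @rdname accessors
#' @export
setGeneric("borderStrength", function(x) standardGeneric("borderStrength"))
#' @rdname accessors
#' @export
setMethod("borderStrength", "TadPartition", function(x) x@strength)

#' @rdname accessors
#' @export
setGeneric("borderProminence", function(x) standardGeneric("borderProminence"))
#' @rdname accessors
#' @export
setMethod("borderProminence", "TadPartition", function(x) x@prominence)

#' @rdname accessors
#' @export
setGeneric("plantedDomains", function(x, condition) standardGeneric("plantedDomains"))
#' @rdname accessors
#' @export
setMethod("plantedDomains", "SyntheticTruth",
    function(x, condition) x@plantedELads[[condition]])

#' @importFrom BiocGenerics conditions
#' @export
BiocGenerics::conditions

#' @rdname accessors
#' @export
setMethod("conditions", "SyntheticTruth", function(object) object@conditions)
#' @rdname accessors
#' @export
setMethod("conditions", "DynamicsSummary", function(object) object@conditions)

#' @rdname accessors
#' @export
setGeneric("oddsRatio", function(x) standardGeneric("oddsRatio"))
#' @rdname accessors
#' @export
setMethod("oddsRatio", "ContingencyResult", function(x) exp(x@logOdds))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setMethod("pValue", "ContingencyResult", function(x) x@pValue)

setMethod("show", "GenomeModel", function(object) {
    cat(sprintf("GenomeModel: %d chromosome(s), %.1f Mb; %d genes; %d cLADs\n",
        length(object@chromLengths), sum(object@chromLengths) / 1e6,
        length(object@genes), length(object@clads)))
})

setMethod("show", "SyntheticTruth", function(object) {
    cat(sprintf("SyntheticTruth: conditions %s\n",
        paste(object@conditions, collapse = ", ")))
    for (cond in object@conditions) {
        gr <- object@plantedELads[[cond]]
        cat(sprintf("  %s: %d planted eLADs (%.2f Mb), %d TAD boundaries, %d DE genes\n",
            cond, length(gr), sum(BiocGenerics::width(gr)) / 1e6,
            length(object@tadBoundaries[[cond]]),
            length(object@deGenes[[cond]])))
    }
})

setMethod("show", "SignalTrack", function(object) {
    cat(sprintf("SignalTrack: bin %d bp, %d chromosome(s), library size %.3g\n",
        as.integer(object@binSize), length(object@values), object@librarySize))
})

setMethod("show", "PeakSet", function(object) {
    cat(sprintf("PeakSet [%s]: %d peaks, %.2f Mb total\n", object@condition,
        length(object@granges), sum(BiocGenerics::width(object@granges)) / 1e6))
})

setMethod("show", "ELadSet", function(object) {
    n <- length(object@granges)
    meansz <- if (n) mean(BiocGenerics::width(object@granges)) else 0
    cat(sprintf("ELadSet [%s]: %d domains, mean size %.2f Mb\n",
        object@condition, n, meansz / 1e6))
})

setMethod("show", "ContactMatrix", function(object) {
    cat(sprintf("ContactMatrix [%s]: %d bins at %d bp, %d masked, %s\n",
        object@chrom, nrow(object@matrix), as.integer(object@resolution),
        sum(object@mask), if (object@balanced) "balanced" else "raw"))
})

setMethod("show", "CompartmentProfile", function(object) {
    lab <- object@labels
    cat(sprintf("CompartmentProfile [%s]: %d bins at %d bp (A: %d, B: %d, masked: %d)\n",
        object@chrom, length(lab), as.integer(object@resolution),
        sum(lab == "A", na.rm = TRUE), sum(lab == "B", na.rm = TRUE),
        sum(is.na(lab))))
})

setMethod("show", "TadPartition", function(object) {
    cat(sprintf("TadPartition [%s]: %d borders at %d bp (window %d bins)\n",
        object@chrom, length(object@borders), as.integer(object@resolution),
        object@window))
})

setMethod("show", "ContingencyResult", function(object) {
    cat(sprintf("ContingencyResult: %s x %s, log-odds %.3f%s, p = %.3g\n",
        object@feature, object@landmark, object@logOdds,
        if (object@corrected) " (corrected)" else "", object@pValue))
})

setMethod("show", "DynamicsSummary", function(object) {
    cat(sprintf("DynamicsSummary over %s:\n  union %d; maintained %d (%d%%); changed %d (%d%%)\n",
        paste(object@conditions, collapse = ", "),
        object@maintained + object@changed,
        object@maintained, round(100 * object@maintainedFraction),
        object@changed, round(100 * object@changedFraction)))
})
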