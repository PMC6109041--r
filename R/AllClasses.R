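#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom stats ppois pbinom dhyper median quantile rgamma rlnorm rpois
#'   runif rbinom rexp p.adjust setNames cor sd
#' @importFrom utils head tail read.table write.table packageVersion
#'   capture.output str
NULL

#' GenomeModel: the coordinate frame for an analysis
#'
#' Holds chromosome lengths, gene annotations (body, strand, TSS) and
#' constitutive lamina-associated domain (cLAD) intervals. All other objects
#' in the package are interpreted against a GenomeModel.
#'
#' @slot chromLengths Named numeric vector of chromosome lengths in bp.
#' @slot genes A [GenomicRanges::GRanges] of gene bodies with metadata columns
#'   `gene_id` (character, unique) and `tss` (1-based TSS position in bp).
#'   Strand is `+` or `-`; TSS is the 5' end of the body.
#' @slot clads A [GenomicRanges::GRanges] of cLAD intervals.
#'
#' @seealso [simulateGenome()] to build one with planted ground truth.
#' @export
setClass("GenomeModel",
    representation(
        chromLengths = "numeric",
        genes = "GRanges",
        clads = "GRanges"
    )
)

setValidity("GenomeModel", function(object) {
    msgs <- character(0)
    cl <- object@chromLengths
    if (length(cl) > 0 && (is.null(names(cl)) || anyNA(names(cl)) || any(names(cl) == "")))
        msgs <- c(msgs, "chromLengths must be named")
    if (any(cl <= 0)) msgs <- c(msgs, "chromosome lengths must be positive")
    for (gr in list(object@genes, object@clads)) {
        if (length(gr) == 0) next
        chr <- as.character(GenomeInfoDb::seqnames(gr))
        if (!all(chr %in% names(cl))) {
            msgs <- c(msgs, "interval on unknown chromosome")
            next
        }
        if (any(BiocGenerics::start(gr) < 1) ||
            any(BiocGenerics::end(gr) > cl[chr]))
            msgs <- c(msgs, "interval outside chromosome bounds")
    }
    g <- object@genes
    if (length(g) > 0) {
        mc <- S4Vectors::mcols(g)
        if (!all(c("gene_id", "tss") %in% colnames(mc)))
            msgs <- c(msgs, "genes need gene_id and tss metadata columns")
        else {
            if (anyDuplicated(mc$gene_id)) msgs <- c(msgs, "duplicate gene ids")
            bad <- mc$tss < BiocGenerics::start(g) | mc$tss > BiocGenerics::end(g)
            if (any(bad)) msgs <- c(msgs, "TSS outside gene body")
        }
        if (!all(as.character(BiocGenerics::strand(g)) %in% c("+", "-")))
            msgs <- c(msgs, "gene strand must be + or -")
    }
    if (length(msgs)) msgs else TRUE
})

#' SyntheticTruth: planted ground truth for a simulated study
#'
#' Records what the simulators planted so recovery can be scored: per-condition
#' eLAD intervals, per-bin A/B compartment labels, TAD boundary bins, per-gene
#' lamin B1 status, and differentially expressed (DE) gene sets.
#'
#' @slot conditions Character vector of condition labels, in temporal order.
#' @slot plantedELads Named list (one per condition) of GRanges.
#' @slot compartmentLabels Named list of per-bin "A"/"B" character vectors at
#'   `compartmentResolution`.
#' @slot tadBoundaries Named list of strictly increasing 1-based bin indices at
#'   `tadResolution`.
#' @slot geneLaminStatus Named list of named logical vectors (per gene).
#' @slot deGenes Named list of character vectors of gene ids.
#' @slot compartmentResolution,tadResolution Bin sizes in bp.
#' @export
setClass("SyntheticTruth",
    representation(
        conditions = "character",
        plantedELads = "list",
        compartmentLabels = "list",
        tadBoundaries = "list",
        geneLaminStatus = "list",
        deGenes = "list",
        compartmentResolution = "numeric",
        tadResolution = "numeric"
    )
)

setValidity("SyntheticTruth", function(object) {
    msgs <- character(0)
    cond <- object@conditions
    for (slotnm in c("plantedELads", "compartmentLabels", "tadBoundaries",
                     "geneLaminStatus", "deGenes")) {
        x <- slot(object, slotnm)
        if (!identical(sort(names(x)), sort(cond)))
            msgs <- c(msgs, sprintf("%s must have one entry per condition", slotnm))
    }
    for (gr in object@plantedELads) {
        if (length(gr) > 1 && any(IRanges::countOverlaps(gr, gr) > 1))
            msgs <- c(msgs, "planted eLADs must be disjoint within a condition")
    }
    for (b in object@tadBoundaries) {
        if (length(b) > 1 && any(diff(b) <= 0))
            msgs <- c(msgs, "tad boundaries must be strictly increasing")
    }
    for (lab in object@compartmentLabels) {
        if (!all(lab %in% c("A", "B")))
            msgs <- c(msgs, "compartment labels must be A or B")
    }
    if (length(msgs)) unique(msgs) else TRUE
})

#' SignalTrack: fixed-bin-size coverage vectors
#'
#' Per-chromosome vectors of non-negative per-bin values (read counts or
#' normalized signal) on a fixed bin grid, with the library size used for
#' reads-per-million normalization. Bin `i` (1-based) covers base pairs
#' `[(i-1)*binSize, i*binSize)` in 0-based half-open terms.
#'
#' @slot binSize Bin width in bp.
#' @slot values Named list of numeric vectors, one per chromosome, of length
#'   `ceiling(chromLength / binSize)`.
#' @slot librarySize Total count across the track.
#' @export
setClass("SignalTrack",
    representation(
        binSize = "numeric",
        values = "list",
        librarySize = "numeric"
    )
)

setValidity("SignalTrack", function(object) {
    msgs <- character(0)
    if (length(object@binSize) != 1 || object@binSize <= 0)
        msgs <- c(msgs, "binSize must be a positive scalar")
    if (is.null(names(object@values)) && length(object@values) > 0)
        msgs <- c(msgs, "values must be named by chromosome")
    if (any(vapply(object@values, function(v) any(v < 0), logical(1))))
        msgs <- c(msgs, "per-bin values must be non-negative")
    if (object@librarySize < 0) msgs <- c(msgs, "librarySize must be >= 0")
    if (length(msgs)) msgs else TRUE
})

#' PeakSet: significant lamin B1-positive sites
#'
#' Sorted, non-overlapping intervals with a MACS-style score
#' (-log10 adjusted p) and mean fold enrichment over the control rate.
#'
#' @slot condition Condition label.
#' @slot granges GRanges with metadata columns `score` and `fold`.
#' @export
setClass("PeakSet",
    representation(condition = "character", granges = "GRanges")
)

setValidity("PeakSet", function(object) {
    msgs <- character(0)
    gr <- object@granges
    if (length(gr) > 0) {
        mc <- S4Vectors::mcols(gr)
        if (!all(c("score", "fold") %in% colnames(mc)))
            msgs <- c(msgs, "peaks need score and fold metadata columns")
        else if (any(mc$score < 0)) msgs <- c(msgs, "scores must be >= 0")
        if (S4Vectors::isSorted(gr) == FALSE)
            msgs <- c(msgs, "peaks must be sorted")
        if (length(gr) > 1 && any(IRanges::countOverlaps(gr, gr) > 1))
            msgs <- c(msgs, "peaks must be non-overlapping")
    }
    if (length(msgs)) msgs else TRUE
})

#' ELadSet: euchromatin lamin B1-associated domains
#'
#' Gap-merged clusters of lamin B1+ sites; each domain carries the number of
#' member sites. Domains are sorted and disjoint.
#'
#' @slot condition Condition label.
#' @slot granges GRanges with metadata column `siteCount`.
#' @slot minSites The site-count threshold the set was called with.
#' @export
setClass("ELadSet",
    representation(condition = "character", granges = "GRanges",
                   minSites = "numeric")
)

setValidity("ELadSet", function(object) {
    msgs <- character(0)
    gr <- object@granges
    if (length(gr) > 0) {
        if (!"siteCount" %in% colnames(S4Vectors::mcols(gr)))
            msgs <- c(msgs, "domains need a siteCount metadata column")
        else if (any(S4Vectors::mcols(gr)$siteCount < object@minSites))
            msgs <- c(msgs, "every domain must satisfy minSites")
        if (length(gr) > 1 && any(IRanges::countOverlaps(gr, gr) > 1))
            msgs <- c(msgs, "domains must be disjoint")
    }
    if (length(msgs)) msgs else TRUE
})

#' ContactMatrix: a binned intra-chromosomal Hi-C map
#'
#' Square symmetric matrix of non-negative contact counts (or balanced values)
#' at a fixed resolution, with a mask for low-coverage bins that are excluded
#' from all downstream statistics.
#'
#' @slot chrom Chromosome name.
#' @slot resolution Bin size in bp.
#' @slot matrix Square numeric matrix.
#' @slot mask Logical vector, TRUE = bin masked (excluded).
#' @slot balanced Whether iterative correction has been applied.
#' @export
setClass("ContactMatrix",
    representation(chrom = "character", resolution = "numeric",
                   matrix = "matrix", mask = "logical", balanced = "logical")
)

setValidity("ContactMatrix", function(object) {
    msgs <- character(0)
    m <- object@matrix
    if (nrow(m) != ncol(m)) msgs <- c(msgs, "matrix must be square")
    if (length(object@mask) != nrow(m))
        msgs <- c(msgs, "mask length must equal matrix dimension")
    if (any(m < 0, na.rm = TRUE)) msgs <- c(msgs, "contacts must be non-negative")
    tolcheck <- if (object@balanced) 1e-8 * max(abs(m), 1) else 0
    if (max(abs(m - t(m))) > tolcheck)
        msgs <- c(msgs, "matrix must be symmetric")
    if (length(msgs)) msgs else TRUE
})

#' CompartmentProfile: per-bin PC1 and A/B labels
#'
#' Leading eigenvector of the observed/expected correlation matrix, oriented
#' so that positive PC1 (label "A") is the gene-dense/active state.
#'
#' @slot chrom Chromosome name.
#' @slot resolution Bin size in bp.
#' @slot pc1 Numeric vector (NA at masked bins).
#' @slot labels Character vector "A"/"B" (NA at masked bins).
#' @slot orientationCor Correlation of oriented PC1 with the orientation
#'   covariate (always >= 0 after orientation).
#' @export
setClass("CompartmentProfile",
    representation(chrom = "character", resolution = "numeric",
                   pc1 = "numeric", labels = "character",
                   orientationCor = "numeric")
)

setValidity("CompartmentProfile", function(object) {
    msgs <- character(0)
    if (length(object@pc1) != length(object@labels))
        msgs <- c(msgs, "pc1 and labels must have the same length")
    ok <- !is.na(object@pc1)
    lab <- ifelse(object@pc1[ok] > 0, "A", "B")
    if (!identical(lab, object@labels[ok]))
        msgs <- c(msgs, "label must be A iff PC1 > 0")
    if (length(msgs)) msgs else TRUE
})

#' TadPartition: insulation vector and TAD borders with strength
#'
#' Borders are local minima of the insulation score; strength is prominence
#' normalized to (0, 10] per chromosome, so the strongest border scores 10.
#'
#' @slot chrom Chromosome name.
#' @slot resolution Bin size in bp.
#' @slot insulation Per-bin log2 insulation score (NA near edges/masked bins).
#' @slot borders Strictly increasing 1-based bin indices.
#' @slot strength Numeric vector in (0, 10], parallel to `borders`.
#' @slot prominence Raw insulation prominence (log2 units) per border; the
#'   scale-free `strength` is this rescaled to 10 at the chromosome maximum,
#'   so cross-condition comparisons should use `prominence`.
#' @slot window Insulation window in bins.
#' @export
setClass("TadPartition",
    representation(chrom = "character", resolution = "numeric",
                   insulation = "numeric", borders = "integer",
                   strength = "numeric", prominence = "numeric",
                   window = "integer")
)

setValidity("TadPartition", function(object) {
    msgs <- character(0)
    if (length(object@borders) != length(object@strength) ||
        length(object@borders) != length(object@prominence))
        msgs <- c(msgs, "borders, strength and prominence must be parallel")
    if (length(object@borders) > 1 && any(diff(object@borders) <= 0))
        msgs <- c(msgs, "border indices must be strictly increasing")
    if (length(object@strength) > 0 &&
        (any(object@strength <= 0) || any(object@strength > 10 + 1e-9)))
        msgs <- c(msgs, "strength must lie in (0, 10]")
    if (length(msgs)) msgs else TRUE
})

#' ContingencyResult: one feature x landmark 2x2 test
#'
#' @slot feature Feature name (e.g. "eLAD").
#' @slot landmark Landmark name (e.g. "A", "B", "border").
#' @slot counts 2x2 integer matrix: rows feature +/-, columns in/out landmark.
#' @slot logOdds Natural-log odds ratio (Haldane-Anscombe corrected only when
#'   a zero cell exists).
#' @slot pValue Two-sided Fisher exact p-value.
#' @slot corrected Whether the 1/2 correction was applied.
#' @export
setClass("ContingencyResult",
    representation(feature = "character", landmark = "character",
                   counts = "matrix", logOdds = "numeric", pValue = "numeric",
                   corrected = "logical")
)

setValidity("ContingencyResult", function(object) {
    msgs <- character(0)
    if (!identical(dim(object@counts), c(2L, 2L)))
        msgs <- c(msgs, "counts must be 2x2")
    if (any(object@counts < 0)) msgs <- c(msgs, "counts must be non-negative")
    if (object@pValue <= 0 || object@pValue > 1)
        msgs <- c(msgs, "p-value must lie in (0, 1]")
    if (!is.finite(object@logOdds)) msgs <- c(msgs, "log-odds must be finite")
    if (length(msgs)) msgs else TRUE
})

#' DynamicsSummary: lamin B1 target-gene set dynamics across conditions
#'
#' Venn-region counts across the per-condition target sets, the maintained
#' (present in every condition) and changed (union minus intersection) counts,
#' and their fractions of the union.
#'
#' @slot conditions Condition labels.
#' @slot sets Named list of gene-id character vectors.
#' @slot vennCounts Named numeric of disjoint Venn-region sizes.
#' @slot maintained,changed Counts.
#' @slot maintainedFraction,changedFraction Exact fractions of the union.
#' @export
setClass("DynamicsSummary",
    representation(conditions = "character", sets = "list",
                   vennCounts = "numeric", maintained = "numeric",
                   changed = "numeric", maintainedFraction = "numeric",
                   changedFraction = "numeric")
)

setValidity("DynamicsSummary", function(object) {
    msgs <- character(0)
    unionSize <- length(unique(unlist(object@sets)))
    if (sum(object@vennCounts) != unionSize)
        msgs <- c(msgs, "venn regions must sum to union size")
    if (object@maintained + object@changed != unionSize)
        msgs <- c(msgs, "maintained + changed must equal union size")
    fr <- c(object@maintainedFraction, object@changedFraction)
    if (any(fr < 0 | fr > 1)) msgs <- c(msgs, "fractions must lie in [0,1]")
    if (length(msgs)) msgs else TRUE
})
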