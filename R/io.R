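# File formats. Every file written by the package uses 0-based half-open
# coordinates (the BED convention); internal GRanges are 1-based closed, and
# these readers/writers are the single place where the conversion happens.

#' Read a BED3/4/6 file
#'
#' @param path Path to a BED file (0-based half-open).
#' @param chromLengths Optional named lengths to attach as seqinfo.
#' @return GRanges; a BED4 `name` column becomes metadata column `name`, a
#'   BED6 file also sets strand and a `score` column. Malformed lines (wrong
#'   field count, end <= start) raise an error naming the line.
#' @export
readBed <- function(path, chromLengths = NULL) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
    if (length(lines) == 0) return(.emptyGR(chromLengths))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3))
        stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
    chrom <- vapply(fields, `[`, character(1), 1)
    start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2)))
    end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3)))
    bad <- which(is.na(start0) | is.na(end0) | end0 <= start0)
    if (length(bad) > 0)
        stop("malformed BED line ", bad[1], ": end <= start or non-numeric")
    cl <- if (is.null(chromLengths))
        setNames(rep(NA_real_, length(unique(chrom))), unique(chrom))
    else chromLengths
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = start0 + 1, end = end0))
    if (!is.null(chromLengths)) {
        GenomeInfoDb::seqlevels(gr) <- names(chromLengths)
        GenomeInfoDb::seqlengths(gr) <- unname(chromLengths)
    }
    if (all(nf >= 4))
        S4Vectors::mcols(gr)$name <- vapply(fields, `[`, character(1), 4)
    if (all(nf >= 6)) {
        S4Vectors::mcols(gr)$score <-
            suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 5)))
        st <- vapply(fields, `[`, character(1), 6)
        if (!all(st %in% c("+", "-", ".")))
            stop("malformed BED strand field")
        BiocGenerics::strand(gr) <- st
    }
    gr
}

#' Write intervals as BED
#'
#' @param gr GRanges (metadata columns `name` and `score` used when present;
#'   strand written for BED6).
#' @param path Output path.
#' @param format "bed3", "bed4" or "bed6".
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path, format = c("bed3", "bed4", "bed6")) {
    format <- match.arg(format)
    chrom <- as.character(GenomeInfoDb::seqnames(gr))
    start0 <- format(BiocGenerics::start(gr) - 1, scientific = FALSE, trim = TRUE)
    end0 <- format(BiocGenerics::end(gr), scientific = FALSE, trim = TRUE)
    mc <- S4Vectors::mcols(gr)
    name <- if ("name" %in% colnames(mc)) as.character(mc$name)
            else rep(".", length(gr))
    lines <- switch(format,
        bed3 = paste(chrom, start0, end0, sep = "\t"),
        bed4 = paste(chrom, start0, end0, name, sep = "\t"),
        bed6 = {
            score <- if ("score" %in% colnames(mc)) mc$score
                     else rep(0, length(gr))
            st <- as.character(BiocGenerics::strand(gr))
            st[st == "*"] <- "."
            paste(chrom, start0, end0, name,
                  format(score, scientific = FALSE, trim = TRUE), st,
                  sep = "\t")
        })
    writeLines(lines, path)
    invisible(path)
}

#' Write a peak set as BED6 with a MACS-style score
#'
#' Score column is `-10 * log10(q)` capped at 1000.
#'
#' @param peakset A [PeakSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePeaksBed <- function(peakset, path) {
    gr <- peaks(peakset)
    out <- GenomicRanges::granges(gr)
    S4Vectors::mcols(out)$name <- sprintf("%s_peak_%d", peakset@condition,
                                          seq_along(gr))
    S4Vectors::mcols(out)$score <-
        round(pmin(10 * S4Vectors::mcols(gr)$score, 1000))
    writeBed(out, path, "bed6")
}

#' Read a fixed-bin bedGraph into a SignalTrack
#'
#' Records must lie on a regular grid of `binSize` (an inconsistent grid is
#' an error); missing bins are zero-filled.
#'
#' @param path bedGraph path (0-based half-open).
#' @param binSize Declared bin size in bp.
#' @param chromLengths Named chromosome lengths.
#' @return A [SignalTrack] (librarySize = sum of values).
#' @export
readBedGraph <- function(path, binSize, chromLengths) {
    tab <- read.table(path, sep = "\t", header = FALSE,
                      col.names = c("chrom", "start", "end", "value"),
                      colClasses = c("character", "numeric", "numeric",
                                     "numeric"))
    if (any(tab$start %% binSize != 0))
        stop("bedGraph records do not lie on the declared bin grid")
    if (any(tab$end - tab$start > binSize))
        stop("bedGraph record wider than the declared bin size")
    vals <- lapply(names(chromLengths), function(chr) {
        n <- ceiling(chromLengths[[chr]] / binSize)
        v <- numeric(n)
        rows <- tab[tab$chrom == chr, , drop = FALSE]
        if (nrow(rows) > 0) {
            idx <- rows$start / binSize + 1
            if (any(idx > n)) stop("bedGraph record beyond chromosome end")
            v[idx] <- rows$value
        }
        v
    })
    names(vals) <- names(chromLengths)
    new("SignalTrack", binSize = binSize, values = vals,
        librarySize = sum(unlist(vals)))
}

#' Write a SignalTrack as bedGraph (zero bins omitted)
#'
#' @param track A [SignalTrack].
#' @param path Output path.
#' @param chromLengths Named chromosome lengths (to clip the last bin).
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(track, path, chromLengths) {
    bs <- track@binSize
    con <- file(path, "w")
    on.exit(close(con))
    for (chr in names(track@values)) {
        v <- track@values[[chr]]
        nz <- which(v != 0)
        if (length(nz) == 0) next
        start0 <- (nz - 1) * bs
        end0 <- pmin(nz * bs, chromLengths[[chr]])
        writeLines(paste(chr,
            format(start0, scientific = FALSE, trim = TRUE),
            format(end0, scientific = FALSE, trim = TRUE),
            format(v[nz], scientific = FALSE, trim = TRUE), sep = "\t"), con)
    }
    invisible(path)
}

#' Read a dense contact matrix with its sidecar header
#'
#' The matrix is whitespace-delimited; the sidecar `<path>.hdr` holds
#' `chrom`, `resolution` and `n_bins` (one `key<TAB>value` pair per line).
#' The matrix must be square of size `n_bins`. An asymmetric matrix within
#' relative tolerance `symTol` is symmetrized with a warning; beyond it, an
#' error.
#'
#' @param path Matrix path (`<path>.hdr` must exist).
#' @param symTol Relative asymmetry tolerance (default 1e-6).
#' @return A [ContactMatrix] (raw, no bins masked).
#' @export
readContactMatrix <- function(path, symTol = 1e-6) {
    hdrPath <- paste0(path, ".hdr")
    if (!file.exists(hdrPath)) stop("missing sidecar header: ", hdrPath)
    hdr <- read.table(hdrPath, sep = "\t", header = FALSE,
                      col.names = c("key", "value"),
                      colClasses = "character")
    get <- function(k) {
        i <- match(k, hdr$key)
        if (is.na(i)) stop("header missing key: ", k)
        hdr$value[i]
    }
    chrom <- get("chrom")
    res <- as.numeric(get("resolution"))
    nBins <- as.integer(get("n_bins"))
    m <- as.matrix(read.table(path, header = FALSE))
    dimnames(m) <- NULL
    if (nrow(m) != nBins || ncol(m) != nBins)
        stop(sprintf("matrix is %dx%d but header declares %d bins",
                     nrow(m), ncol(m), nBins))
    if (any(m < 0)) stop("negative contact values")
    asym <- max(abs(m - t(m))) / max(abs(m), 1e-12)
    if (asym > 0) {
        if (asym > symTol)
            stop(sprintf("matrix asymmetric beyond tolerance (rel. err %.3g)",
                         asym))
        warning("matrix slightly asymmetric; symmetrizing")
        m <- (m + t(m)) / 2
    }
    new("ContactMatrix", chrom = chrom, resolution = res, matrix = m,
        mask = rep(FALSE, nBins), balanced = FALSE)
}

#' Write a contact matrix and its sidecar header
#'
#' @param cm A [ContactMatrix].
#' @param path Output path (header goes to `<path>.hdr`).
#' @return `path`, invisibly.
#' @export
writeContactMatrix <- function(cm, path) {
    write.table(cm@matrix, path, sep = " ", row.names = FALSE,
                col.names = FALSE)
    writeLines(c(paste0("chrom\t", cm@chrom),
                 paste0("resolution\t",
                        format(cm@resolution, scientific = FALSE)),
                 paste0("n_bins\t", nrow(cm@matrix))),
               paste0(path, ".hdr"))
    invisible(path)
}

#' Read an expression TSV (gene_id + fpkm_<condition> columns)
#'
#' @param path TSV path with a header line.
#' @param genome Optional [GenomeModel]; genes absent from it raise an error
#'   listing the offending ids.
#' @return data.frame ExpressionTable.
#' @export
readExpression <- function(path, genome = NULL) {
    tab <- read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE)
    if (!"gene_id" %in% colnames(tab)) stop("missing gene_id column")
    fcols <- grep("^fpkm_", colnames(tab), value = TRUE)
    if (length(fcols) == 0) stop("no fpkm_<condition> columns")
    if (any(unlist(tab[fcols]) < 0)) stop("negative FPKM values")
    if (!is.null(genome)) {
        known <- S4Vectors::mcols(genes(genome))$gene_id
        unknown <- setdiff(tab$gene_id, known)
        if (length(unknown) > 0)
            stop("genes absent from the genome model: ",
                 paste(head(unknown, 5), collapse = ", "),
                 if (length(unknown) > 5) ", ..." else "")
    }
    tab
}

#' Write an expression table as TSV
#'
#' @param expr ExpressionTable data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(expr, path) {
    write.table(expr, path, sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Write a GenomeModel's genes as BED6 and cLADs as BED3
#'
#' @param genome A [GenomeModel].
#' @param genesPath,cladsPath Output paths (NULL to skip either).
#' @return Invisibly, the paths written.
#' @export
writeGenomeModel <- function(genome, genesPath = NULL, cladsPath = NULL) {
    if (!is.null(genesPath)) {
        g <- genes(genome)
        out <- GenomicRanges::granges(g)
        S4Vectors::mcols(out)$name <- S4Vectors::mcols(g)$gene_id
        S4Vectors::mcols(out)$score <- rep(0, length(g))
        writeBed(out, genesPath, "bed6")
    }
    if (!is.null(cladsPath))
        writeBed(clads(genome), cladsPath, "bed3")
    invisible(c(genesPath, cladsPath))
}
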