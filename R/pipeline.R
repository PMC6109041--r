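#' Default pipeline configuration
#'
#' Returns the full nested configuration for [runPipeline()] with the
#' package's default study conditions: one 20-Mb chromosome, three conditions,
#' planted eLADs of mean 0.34 Mb, ChIP enrichment 4 at depth 1e6, compartment
#' matrices at 100 kb and TAD matrices at 40 kb. Every entry can be
#' overridden; unknown keys are rejected by [runPipeline()].
#'
#' @param seed Integer seed recorded in the config.
#' @return Nested list of stage parameter blocks.
#' @export
defaultPipelineConfig <- function(seed = 1) {
    list(
        seed = seed,
        simulate = list(
            enabled = TRUE,
            # a named list (not vector) so YAML round trips keep the names
            chromLengths = list(chr1 = 2e7),
            nGenes = 600,
            cladFraction = 0.2,
            nDomains = 12,
            meanDomainSize = 3.4e5,
            conditions = c("untreated", "tgfb_8h", "tgfb_24h"),
            retention = 0.28
        ),
        chip = list(depth = 1e6, enrichment = 4, binSize = 1000,
                    tssBump = 1.5),
        sites = list(fdr = 0.05, minFold = 2),
        elads = list(maxGap = 1e5, minSites = 3),
        expression = list(shift = 1.5, silentFraction = 0.15,
                          silentThreshold = 0.5),
        targets = list(tssWindow = 2000),
        hic = list(enabled = TRUE, compartmentFactor = 1.5, tadFactor = 2.5,
                   depthScale = 100, window = 5, prominenceMin = 0.5,
                   borderSpan = 1, matchTol = 2, minAbsPc1 = 0)
    )
}

.checkConfig <- function(config) {
    ref <- defaultPipelineConfig()
    unknownTop <- setdiff(names(config), names(ref))
    if (length(unknownTop) > 0)
        stop("unknown config keys: ", paste(unknownTop, collapse = ", "))
    for (blk in intersect(names(config), names(ref))) {
        if (!is.list(ref[[blk]])) next
        unknown <- setdiff(names(config[[blk]]), names(ref[[blk]]))
        if (length(unknown) > 0)
            stop(sprintf("unknown config keys in %s: %s", blk,
                         paste(unknown, collapse = ", ")))
    }
    merged <- ref
    for (blk in names(config)) {
        if (is.list(ref[[blk]]))
            merged[[blk]][names(config[[blk]])] <- config[[blk]]
        else merged[[blk]] <- config[[blk]]
    }
    merged
}

#' Run the full eLAD analysis pipeline on simulated data
#'
#' Executes simulate, call-sites, call-elads, compartments, TADs,
#' integration and dynamics in order, collecting every summary number into a
#' machine-readable report. When `outdir` is given, per-stage files (peaks and
#' eLADs as BED, tracks as bedGraph, borders as TSV, contact matrices with
#' sidecar headers) and `report.json` are written there together with a log
#' recording the seed and full parameter set. A stage failure aborts with the
#' stage name. With `hic$enabled = FALSE` the ChIP-only stages still run and
#' the report marks the Hi-C stages as skipped.
#'
#' @param config Configuration list (see [defaultPipelineConfig()]) or a path
#'   to a YAML file holding one. Unknown keys are rejected.
#' @param outdir Optional output directory (created if needed).
#' @return The report, a nested list (also serialized to JSON in `outdir`).
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outdir = NULL) {
    if (is.character(config))
        config <- yaml::read_yaml(config)
    cfg <- .checkConfig(config)
    cfg$simulate$chromLengths <- unlist(cfg$simulate$chromLengths)
    if (!isTRUE(cfg$simulate$enabled))
        stop("stage simulate: only the simulated-input mode is supported; ",
             "use the module functions directly for external files")
    seed <- cfg$seed
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 call. = FALSE))
    }
    if (!is.null(outdir) && !dir.exists(outdir))
        dir.create(outdir, recursive = TRUE)

    sim <- stage("simulate", do.call(simulateGenome, c(
        cfg$simulate[setdiff(names(cfg$simulate), "enabled")],
        list(seed = seed))))
    genome <- sim$genome
    truth <- sim$truth
    conds <- conditions(truth)
    cl <- chromLengths(genome)
    chrom <- names(cl)[1]

    report <- list(
        package = "eladkit",
        version = as.character(utils::packageVersion("eladkit")),
        seed = seed,
        parameters = cfg[setdiff(names(cfg), "seed")],
        conditions = conds
    )

    expr <- stage("expression", simulateExpression(genome, truth,
        shift = cfg$expression$shift,
        silentFraction = cfg$expression$silentFraction,
        seed = .subSeed(seed, "expression")))

    peakSets <- list(); eladSets <- list(); targetSets <- list()
    condReport <- list()
    for (cond in conds) {
        tr <- stage("call-sites", simulateChipTracks(genome, truth, cond,
            depth = cfg$chip$depth, enrichment = cfg$chip$enrichment,
            binSize = cfg$chip$binSize, tssBump = cfg$chip$tssBump,
            seed = .subSeed(seed, paste0("chip_", cond))))
        pk <- stage("call-sites", callSites(tr$chip, tr$control,
            fdr = cfg$sites$fdr, minFold = cfg$sites$minFold,
            condition = cond))
        el <- stage("call-elads", callELads(pk, maxGap = cfg$elads$maxGap,
            minSites = cfg$elads$minSites))
        tg <- stage("dynamics", assignTargetGenes(pk, genome,
            tssWindow = cfg$targets$tssWindow))
        peakSets[[cond]] <- pk
        eladSets[[cond]] <- el
        targetSets[[cond]] <- tg
        ds <- domainSummary(el, genome)
        strat <- stratifyExpression(expr, cond,
            silentThreshold = cfg$expression$silentThreshold)
        rec <- intervalOverlapStats(domains(el), plantedDomains(truth, cond))
        jac <- rec$jaccard
        condReport[[cond]] <- list(
            nPeaks = length(peaks(pk)),
            peakBp = sum(as.numeric(BiocGenerics::width(peaks(pk)))),
            nTargets = length(tg),
            nDomains = unname(ds["nDomains"]),
            meanDomainSize = unname(ds["meanSize"]),
            genomeCoverage = unname(ds["coverage"]),
            plantedJaccard = jac,
            strata = as.list(table(strat))
        )
        if (!is.null(outdir)) {
            writePeaksBed(pk, file.path(outdir, paste0("peaks_", cond, ".bed")))
            dom <- GenomicRanges::granges(domains(el))
            S4Vectors::mcols(dom)$name <-
                as.character(S4Vectors::mcols(domains(el))$siteCount)
            writeBed(dom, file.path(outdir, paste0("elads_", cond, ".bed")),
                     "bed4")
            writeBedGraph(tr$chip,
                file.path(outdir, paste0("chip_", cond, ".bedGraph")), cl)
        }
    }
    report$perCondition <- condReport

    dyn <- stage("dynamics", timepointDynamics(targetSets))
    deOv <- lapply(conds, function(cond) {
        r <- deTargetOverlap(truth@deGenes[[cond]], targetSets[[cond]])
        list(overlap = r$overlap, pctTargetsDE = r$pctTargetsDE,
             pctDETargets = r$pctDETargets)
    })
    names(deOv) <- conds
    report$dynamics <- list(
        vennCounts = as.list(dyn@vennCounts),
        maintained = dyn@maintained,
        changed = dyn@changed,
        pctMaintained = round(100 * dyn@maintainedFraction),
        pctChanged = round(100 * dyn@changedFraction),
        deOverlap = deOv
    )
    report$eladDynamics <- {
        cmp <- compareELadSets(eladSets)
        lapply(cmp, function(x) lapply(x, length))
    }

    if (isTRUE(cfg$hic$enabled)) {
        compRes <- truth@compartmentResolution
        tadRes <- truth@tadResolution
        covar <- geneDensityCovariate(genome, chrom, compRes)
        profiles <- list(); partitions <- list(); hicReport <- list()
        for (cond in conds) {
            cmC <- stage("compartments", simulateHic(genome, truth, cond,
                resolution = compRes, chrom = chrom,
                compartmentFactor = cfg$hic$compartmentFactor,
                tadFactor = cfg$hic$tadFactor,
                depthScale = cfg$hic$depthScale,
                seed = .subSeed(seed, paste0("hic100_", cond))))
            balC <- stage("compartments", balanceMatrix(cmC))
            prof <- stage("compartments", compartmentPC1(balC, covar))
            cmT <- stage("tads", simulateHic(genome, truth, cond,
                resolution = tadRes, chrom = chrom,
                compartmentFactor = cfg$hic$compartmentFactor,
                tadFactor = cfg$hic$tadFactor,
                depthScale = cfg$hic$depthScale,
                seed = .subSeed(seed, paste0("hic40_", cond))))
            balT <- stage("tads", balanceMatrix(cmT))
            part <- stage("tads", callBorders(balT, window = cfg$hic$window,
                prominenceMin = cfg$hic$prominenceMin))
            profiles[[cond]] <- prof
            partitions[[cond]] <- part
            enr <- stage("integrate", borderEnrichmentPvalue(
                peakSets[[cond]], part, genome, method = "binomial",
                span = cfg$hic$borderSpan))
            occ <- stage("integrate", borderPeakOccupancy(part,
                peakSets[[cond]], cl[[chrom]], span = cfg$hic$borderSpan))
            lab <- compartmentLabels(prof)
            landmarks <- list(
                A = which(lab == "A"),
                B = which(lab == "B"),
                border = which(.binOverlapIndicator(
                    as.integer(ceiling(cl[[chrom]] / compRes)), compRes,
                    borderIntervals(part, cl[[chrom]], cfg$hic$borderSpan),
                    chrom)))
            features <- list(sites = peaks(peakSets[[cond]]),
                             eLADs = domains(eladSets[[cond]]),
                             cLADs = clads(genome))
            masked <- which(is.na(lab))
            contingency <- list()
            for (fn in names(features)) for (ln in names(landmarks)) {
                res <- try(featureLandmarkLogOdds(features[[fn]],
                    landmarks[[ln]], cl[[chrom]], chrom, compRes,
                    maskedBins = masked, feature = fn, landmark = ln),
                    silent = TRUE)
                if (!inherits(res, "try-error"))
                    contingency[[paste(fn, ln, sep = "_x_")]] <-
                        list(logOdds = res@logOdds, p = res@pValue)
            }
            hicReport[[cond]] <- list(
                nA = sum(lab == "A", na.rm = TRUE),
                nB = sum(lab == "B", na.rm = TRUE),
                nBorders = length(borders(part)),
                borderEnrichmentP = enr$pValue,
                borderEnrichmentFold = enr$fold,
                borderOccupancy = as.list(occ$histogram),
                contingency = contingency
            )
            if (!is.null(outdir)) {
                writeContactMatrix(cmC,
                    file.path(outdir, paste0("hic_comp_", cond, ".matrix")))
                bt <- data.frame(chrom = chrom, bin = borders(part),
                    position0 = (borders(part) - 1) * tadRes,
                    strength = borderStrength(part),
                    insulation = insulation(part)[borders(part)])
                write.table(bt,
                    file.path(outdir, paste0("borders_", cond, ".tsv")),
                    sep = "\t", row.names = FALSE, quote = FALSE)
            }
        }
        changes <- list()
        for (cond in conds[-1]) {
            ch <- stage("compartments", classifyBinChanges(
                profiles[[conds[1]]], profiles[[cond]],
                minAbsPc1 = cfg$hic$minAbsPc1))
            changes[[paste(conds[1], "vs", cond)]] <- as.list(ch$counts)
        }
        mb <- stage("tads", matchBorders(partitions, tol = cfg$hic$matchTol))
        report$hic <- list(
            skipped = FALSE,
            perCondition = hicReport,
            compartmentChanges = changes,
            conservedBorderFraction = mb$conservedFraction
        )
    } else {
        report$hic <- list(skipped = TRUE,
                           reason = "hic disabled in configuration")
    }

    if (!is.null(outdir)) {
        writeExpression(expr, file.path(outdir, "expression.tsv"))
        writeGenomeModel(genome, file.path(outdir, "genes.bed"),
                         file.path(outdir, "clads.bed"))
        jsonlite::write_json(report, file.path(outdir, "report.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE,
                             null = "null")
        writeLines(c(
            sprintf("eladkit %s", report$version),
            sprintf("seed: %d", seed),
            sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
            "parameters:",
            utils::capture.output(utils::str(cfg))),
            file.path(outdir, "pipeline.log"))
    }
    invisible(report)
}

#' Validate a pipeline report against the expected schema
#'
#' Checks that every required top-level and per-condition field is present.
#'
#' @param report A report list as returned by [runPipeline()] (or parsed back
#'   from `report.json`).
#' @return TRUE, invisibly; missing fields raise an error.
#' @export
validateReport <- function(report) {
    need <- c("package", "version", "seed", "parameters", "conditions",
              "perCondition", "dynamics", "hic")
    missing <- setdiff(need, names(report))
    if (length(missing) > 0)
        stop("report missing fields: ", paste(missing, collapse = ", "))
    condNeed <- c("nPeaks", "nTargets", "nDomains", "meanDomainSize",
                  "genomeCoverage")
    for (cond in report$conditions) {
        pc <- report$perCondition[[cond]]
        if (is.null(pc)) stop("report missing condition block: ", cond)
        miss <- setdiff(condNeed, names(pc))
        if (length(miss) > 0)
            stop(sprintf("condition %s missing fields: %s", cond,
                         paste(miss, collapse = ", ")))
    }
    dynNeed <- c("maintained", "changed", "pctMaintained", "deOverlap")
    miss <- setdiff(dynNeed, names(report$dynamics))
    if (length(miss) > 0)
        stop("dynamics block missing fields: ", paste(miss, collapse = ", "))
    if (!isTRUE(report$hic$skipped) &&
        is.null(report$hic$conservedBorderFraction))
        stop("hic block missing conservedBorderFraction")
    invisible(TRUE)
}
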