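# Site caller and the gene-centric summaries.

test_that("identical chip and control tracks yield no peaks", {
    set.seed(42)
    v <- rpois(2000, 30)
    chip <- SignalTrack(v, binSize = 1000)
    ctrl <- SignalTrack(v, binSize = 1000)
    pk <- callSites(chip, ctrl, condition = "null")
    expect_length(peaks(pk), 0)
})

test_that("a strongly enriched bin is called, matching the Poisson tail", {
    n <- 500
    ctrl <- SignalTrack(rep(10, n), binSize = 1000)
    cv <- rep(10, n); cv[250] <- 100
    chip <- SignalTrack(cv, binSize = 1000, librarySize = sum(rep(10, n)))
    # equalize library sizes so the scaled control rate is exactly 10
    pk <- callSites(chip, ctrl, minFold = 2)
    gr <- peaks(pk)
    expect_length(gr, 1)
    expect_true(start(gr) <= 250 * 1000 && end(gr) >= 249 * 1000 + 1)
    # oracle: the exact one-sided Poisson survival probability is tiny
    expect_lt(ppois(99, 10, lower.tail = FALSE), 1e-10)
    expect_gt(mcols(gr)$fold, 2)
})

test_that("degenerate tracks are handled", {
    n <- 100
    zero <- SignalTrack(rep(0, n), binSize = 1000)
    ctrl <- SignalTrack(rep(5, n), binSize = 1000)
    expect_length(peaks(callSites(zero, ctrl)), 0)
    chip <- SignalTrack(rep(5, n), binSize = 1000)
    expect_warning(callSites(chip, zero), "control")
    bad <- SignalTrack(rep(5, n + 1), binSize = 1000)
    expect_error(callSites(chip, bad), "grid")
})

test_that("peak locations are classified with the documented precedence", {
    # + strand gene with TSS at 10000, - strand gene with TSS at 50000
    gm <- fixtureGenome(1e5, geneTable = data.frame(
        start = c(10000, 40001), end = c(19999, 50000),
        strand = c("+", "-")))
    pk <- fixturePeaks(
        starts = c(9650, 8450, 15001, 80001, 51451),
        ends = c(9750, 8550, 15101, 80101, 51551), len = 1e5)
    ann <- annotatePeakLocations(pk, gm)
    byMid <- setNames(as.character(ann$category),
        floor((start(peaks(pk)) + end(peaks(pk))) / 2))
    expect_equal(unname(byMid["9700"]), "proximal")   # 300 bp upstream of +
    expect_equal(unname(byMid["8500"]), "distal")     # 1.5 kb upstream of +
    expect_equal(unname(byMid["15051"]), "intragenic")
    expect_equal(unname(byMid["80051"]), "intergenic")
    expect_equal(unname(byMid["51501"]), "distal")    # 1.5 kb upstream of -
    expect_equal(sum(ann$fractions), 1)
})

test_that("peaks on a gene-free chromosome are intergenic", {
    gm <- fixtureGenome(1e5)
    pk <- fixturePeaks(starts = 5000, ends = 6000, len = 1e5)
    ann <- annotatePeakLocations(pk, gm)
    expect_equal(as.character(ann$category), "intergenic")
})

test_that("target-gene assignment matches a quadratic oracle", {
    set.seed(7)
    nGenes <- 10
    tssPos <- sort(sample(seq(5000, 9.5e5, by = 100), nGenes))
    gm <- fixtureGenome(1e6, geneTable = data.frame(
        start = tssPos, end = tssPos + 5000, strand = "+"))
    expect_identical(assignTargetGenes(fixturePeaks(integer(0), integer(0)),
                                       gm), character(0))
    ids <- mcols(genes(gm))$gene_id
    # peak exactly covering one TSS
    pk1 <- fixturePeaks(tssPos[3], tssPos[3], len = 1e6)
    expect_identical(assignTargetGenes(pk1, gm), ids[3])
    for (rep in 1:5) {
        st <- sort(sample(seq(1, 9.9e5), 8))
        pk <- fixturePeaks(st, st + 999, len = 1e6)
        got <- assignTargetGenes(pk, gm, tssWindow = 2000)
        oracle <- ids[vapply(seq_len(nGenes), function(i) {
            w1 <- tssPos[i] - 2000; w2 <- tssPos[i] + 2000 - 1
            any(st <= w2 & st + 999 >= w1)
        }, logical(1))]
        expect_setequal(got, oracle)
    }
})

test_that("tss metaprofile orients, normalizes and averages correctly", {
    gm <- fixtureGenome(1e5, geneTable = data.frame(
        start = c(20000, 60001), end = c(29999, 70000),
        strand = c("+", "-")))
    ids <- mcols(genes(gm))$gene_id
    n <- 100
    # constant track: flat profile at the RPM value
    const <- SignalTrack(rep(5, n), binSize = 1000)
    prof <- tssMetaprofile(const, ids, gm, flank = 2000)
    expect_length(prof, 4)
    expect_true(all(abs(prof - 5 / librarySize(const) * 1e6) < 1e-9))
    # delta at each TSS: maximal at the first downstream bin
    v <- rep(0, n); v[20] <- 50; v[70] <- 50  # bins holding both TSSs
    delta <- SignalTrack(v, binSize = 1000)
    prof <- tssMetaprofile(delta, ids, gm, flank = 2000)
    expect_equal(which.max(prof), 3)  # center bin (TSS-containing)
    # mirrored signal on opposite strands contributes identically
    v1 <- rep(0, n); v1[21] <- 10          # 1 bin downstream of + TSS
    v2 <- rep(0, n); v2[69] <- 10          # 1 bin "downstream" of - TSS
    p1 <- tssMetaprofile(SignalTrack(v1, binSize = 1000, librarySize = 10),
                         ids[1], gm, flank = 2000)
    p2 <- tssMetaprofile(SignalTrack(v2, binSize = 1000, librarySize = 10),
                         ids[2], gm, flank = 2000)
    expect_equal(p1, p2)
    expect_error(tssMetaprofile(const, character(0), gm), "empty")
})

test_that("expression stratification partitions genes as documented", {
    expr <- data.frame(gene_id = sprintf("g%d", 1:7),
                       fpkm_c1 = c(0, 1, 2, 3, 4, 5, 6))
    s <- stratifyExpression(expr, "c1")
    expect_equal(as.character(s[["g1"]]), "silent")
    expect_equal(unname(table(s)[c("low", "medium", "high")]),
                 rep(2L, 3), ignore_attr = TRUE)
    expect_equal(as.character(s[c("g2", "g3")]), c("low", "low"))
    expect_equal(as.character(s[c("g6", "g7")]), c("high", "high"))
    # rank-preserving relabeling leaves strata unchanged
    expr2 <- expr; expr2$fpkm_c1 <- c(0, 10, 20, 30, 40, 50, 60)
    expect_identical(stratifyExpression(expr2, "c1"), s)
    # all-zero: everything silent
    expr3 <- expr; expr3$fpkm_c1 <- 0
    expect_true(all(stratifyExpression(expr3, "c1") == "silent"))
})

test_that("peak GC content excludes ambiguous bases", {
    seqs <- Biostrings::DNAStringSet(c(chr1 = "ATATGCGCACGTNAAA"))
    pk <- fixturePeaks(starts = c(1, 5, 9), ends = c(4, 8, 13), len = 16)
    res <- peakNucleotideContent(pk, seqs)
    expect_equal(res$gc, c(0, 1, 0.5))
    expect_equal(unname(res$pooled["AT"] + res$pooled["CG"]), 1)
    bad <- fixturePeaks(starts = 10, ends = 20, len = 30)
    expect_error(peakNucleotideContent(bad, seqs), "beyond")
})

test_that("lamin-positive genes show higher TSS signal than negative genes", {
    sim <- defaultSim()
    tr <- simulateChipTracks(sim$genome, sim$truth, "untreated", seed = 9)
    st <- sim$truth@geneLaminStatus[["untreated"]]
    pos <- names(st)[st]; neg <- names(st)[!st]
    pPos <- tssMetaprofile(tr$chip, pos, sim$genome)
    pNeg <- tssMetaprofile(tr$chip, neg, sim$genome)
    expect_gt(mean(pPos), mean(pNeg))
})
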