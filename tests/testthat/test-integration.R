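# Contingency statistics, set dynamics, FRAP arithmetic.

test_that("fisher p and log-odds agree with the independent exact test", {
    # independence: balanced margins
    res <- contingencyTest(20, 20, 10, 10)
    expect_equal(res@logOdds, 0)
    expect_equal(res@pValue, 1)
    # the classic strong-association table
    res <- contingencyTest(30, 10, 10, 30)
    expect_equal(exp(res@logOdds), 9)
    expect_equal(res@logOdds, log(9), tolerance = 1e-12)
    ft <- fisher.test(matrix(c(30, 10, 10, 30), 2))
    expect_equal(res@pValue, ft$p.value, tolerance = 1e-10)
    # zero cell: finite corrected log-odds, p computed normally
    res0 <- contingencyTest(0, 10, 12, 30)
    expect_true(is.finite(res0@logOdds))
    expect_true(res0@corrected)
    ft0 <- fisher.test(matrix(c(0, 10, 12, 30), 2))
    expect_equal(res0@pValue, ft0$p.value, tolerance = 1e-10)
    # random tables cross-checked against stats::fisher.test
    set.seed(11)
    for (rep in 1:50) {
        tb <- as.vector(rmultinom(1, sample(10:80, 1), rep(0.25, 4)))
        p <- fisherExactP(tb[1], tb[2], tb[3], tb[4])
        ft <- fisher.test(matrix(tb, 2, byrow = TRUE))
        expect_equal(p, ft$p.value, tolerance = 1e-10)
    }
})

test_that("feature-by-landmark binning builds the right 2x2 table", {
    # 10 bins of 100 bp; feature covers bins 1-4; landmark = bins 1-5
    feature <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 400))
    res <- featureLandmarkLogOdds(feature, landmarkBins = 1:5,
        chromLength = 1000, chrom = "chr1", resolution = 100,
        feature = "f", landmark = "in")
    expect_equal(unname(res@counts["feature+", "in"]), 4)
    expect_equal(unname(res@counts["feature+", "out"]), 0)
    expect_equal(unname(res@counts["feature-", "in"]), 1)
    expect_equal(unname(res@counts["feature-", "out"]), 5)
    expect_true(res@corrected)
    expect_error(featureLandmarkLogOdds(feature, landmarkBins = 1:10,
        chromLength = 1000, chrom = "chr1", resolution = 100),
        "complement")
})

test_that("border enrichment equals the exact binomial tail", {
    # borders cover exactly 10% of a 300-kb genome: 10 borders x 3 kb
    part <- fixturePartition(seq(5, 275, by = 30), nBins = 300,
                             resolution = 1e3)
    gm <- fixtureGenome(3e5)
    iv <- borderIntervals(part, 3e5)
    expect_equal(sum(width(GenomicRanges::reduce(iv))) / 3e5, 0.1)
    # place 30 peaks inside borders, 70 well outside
    inside <- start(iv)[rep(1:10, each = 3)] + rep(c(0, 500, 1000), 10)
    gaps <- GenomicRanges::setdiff(
        GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 3e5)),
        GenomicRanges::resize(iv, width(iv) + 100, fix = "center"))
    outsideAll <- unlist(mapply(function(s, e) seq(s + 10, e - 60, by = 300),
                                start(gaps), end(gaps)))
    outside <- head(outsideAll, 70)
    pk <- fixturePeaks(c(inside, outside), c(inside, outside) + 49, len = 3e5)
    expect_length(peaks(pk), 100)
    res <- borderEnrichmentPvalue(pk, part, gm, method = "binomial")
    expect_equal(res$observed, 30)
    expect_equal(res$pValue, pbinom(29, 100, 0.1, lower.tail = FALSE))
    expect_equal(res$fold, 3)
    # observed exactly at the null expectation: one-sided p >= 0.5
    at8 <- c(inside[seq(1, 30, by = 4)][1:8], head(outsideAll, 72))
    resNull <- borderEnrichmentPvalue(
        fixturePeaks(at8, at8 + 49, len = 3e5), part, gm,
        method = "binomial")
    expect_equal(resNull$observed, 8)
    expect_gte(resNull$pValue, 0.5)
    # permutation agrees with the binomial within an order of magnitude at a
    # moderate effect size (a strong one saturates the permutation floor)
    at15 <- c(inside[1:15], head(outsideAll, 85))
    pkMild <- fixturePeaks(at15, at15 + 49, len = 3e5)
    resBin <- borderEnrichmentPvalue(pkMild, part, gm, method = "binomial")
    resPerm <- borderEnrichmentPvalue(pkMild, part, gm,
                                      method = "permutation",
                                      nPermutations = 2000, seed = 3)
    expect_lt(abs(log10(resPerm$pValue) - log10(resBin$pValue)), 1)
    # no peaks: p = 1, fold = 0
    none <- borderEnrichmentPvalue(fixturePeaks(integer(0), integer(0)),
                                   part, gm)
    expect_equal(none$pValue, 1)
    expect_equal(none$fold, 0)
})

test_that("timepoint dynamics performs exact set algebra", {
    s <- sprintf("g%d", 1:50)
    same <- timepointDynamics(list(a = s, b = s, c = s))
    expect_equal(same@maintained, 50)
    expect_equal(same@changed, 0)
    expect_equal(same@maintainedFraction, 1)
    dis <- timepointDynamics(list(a = sprintf("a%d", 1:5),
                                  b = sprintf("b%d", 1:7),
                                  c = sprintf("c%d", 1:3)))
    expect_equal(dis@maintained, 0)
    expect_equal(dis@changed, 15)
    # venn regions always sum to the union, fractions recompute exactly
    for (rep in 1:5) {
        set.seed(600 + rep)
        pool <- sprintf("g%d", 1:40)
        sets <- list(a = sample(pool, 20), b = sample(pool, 25),
                     c = sample(pool, 15))
        d <- timepointDynamics(sets)
        un <- length(unique(unlist(sets)))
        expect_equal(sum(d@vennCounts), un)
        expect_equal(d@maintained + d@changed, un)
        expect_equal(d@maintainedFraction, d@maintained / un)
        expect_equal(d@maintained,
                     length(Reduce(intersect, sets)))
    }
})

test_that("de/target overlap reports both directional percentages", {
    dis <- deTargetOverlap(c("a", "b"), c("c", "d"))
    expect_equal(dis$overlap, 0)
    expect_equal(dis$pctTargetsDE, 0)
    expect_equal(dis$pctDETargets, 0)
    empty <- deTargetOverlap(c("a"), character(0))
    expect_true(empty$emptyTargets)
    expect_equal(empty$pctTargetsDE, 0)
    for (rep in 1:5) {
        set.seed(700 + rep)
        pool <- sprintf("g%d", 1:100)
        de <- sample(pool, 40); tg <- sample(pool, 60)
        r <- deTargetOverlap(de, tg)
        expect_equal(r$overlap, sum(tg %in% de))
        expect_equal(r$fracTargetsDE, sum(tg %in% de) / 60)
        expect_equal(r$fracDETargets, sum(de %in% tg) / 40)
    }
})

test_that("frap normalization reproduces hand arithmetic and is scale invariant", {
    expect_equal(frapNormalize(60, 10, 110, 110, 10, 110), 0.5)
    # post-bleach identical to pre-bleach: full recovery = 1
    expect_equal(frapNormalize(80, 10, 110, 80, 10, 110), 1)
    # bleached ROI at background: no recovery = 0
    expect_equal(frapNormalize(10, 10, 110, 110, 10, 110), 0)
    for (c in c(0.5, 3, 100)) {
        expect_equal(frapNormalize(60 * c, 10 * c, 110 * c,
                                   110 * c, 10 * c, 110 * c), 0.5)
    }
    # vectorized over frames
    expect_equal(frapNormalize(c(10, 35, 60), 10, 110, 110, 10, 110),
                 c(0, 0.25, 0.5))
    expect_error(frapNormalize(60, 110, 110, 110, 10, 110), "non-bleached")
})
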