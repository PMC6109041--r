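# Balancing, compartments, insulation, borders, occupancy.

test_that("iterative correction equalizes row sums and respects the mask", {
    set.seed(1)
    n <- 50
    m <- matrix(runif(n * n, 1, 10), n, n)
    m <- m + t(m)
    bal <- balanceMatrix(fixtureContactMatrix(m))
    rs <- rowSums(contactMap(bal))[!binMask(bal)]
    expect_lt(max(abs(rs - mean(rs)) / mean(rs)), 1e-6)
    expect_true(bal@balanced)
    expect_equal(contactMap(bal), t(contactMap(bal)))
    # an already-balanced matrix is a fixed point
    bal2 <- balanceMatrix(bal)
    expect_equal(contactMap(bal2), contactMap(bal), tolerance = 1e-6)
    # an all-zero row is masked and excluded
    m0 <- m; m0[7, ] <- 0; m0[, 7] <- 0
    bal0 <- balanceMatrix(fixtureContactMatrix(m0))
    expect_true(binMask(bal0)[7])
    expect_true(all(contactMap(bal0)[7, ] == 0))
})

test_that("pc1 recovers a noise-free checkerboard exactly and orients by the covariate", {
    sim <- defaultSim()
    g <- sim$genome; tr <- sim$truth
    cm <- simulateHic(g, tr, "untreated", resolution = 1e5, noise = FALSE,
                      seed = 1)
    bal <- balanceMatrix(cm)
    covar <- geneDensityCovariate(g, "chr1", 1e5)
    prof <- compartmentPC1(bal, covar)
    lab <- compartmentLabels(prof)
    planted <- compartmentLabels(tr, "untreated")
    ok <- !is.na(lab)
    expect_true(all(lab[ok] == planted[ok]))
    # negating the covariate flips every label
    flipped <- compartmentPC1(bal, -covar)
    expect_true(all(compartmentLabels(flipped)[ok] !=
                    lab[ok]))
})

test_that("bin-change classification matches an elementwise oracle", {
    p <- fixtureProfile(c(0.5, -0.5, 0.3, NA))
    same <- classifyBinChanges(p, p)
    expect_equal(unname(same$counts), c(0, 0))
    expect_equal(as.character(same$labels),
                 c("stable", "stable", "stable", "masked"))
    q <- fixtureProfile(c(-0.5, -0.5, 0.3, NA))
    one <- classifyBinChanges(p, q)
    expect_equal(unname(one$counts["AtoB"]), 1)
    expect_equal(as.character(one$labels[1]), "AtoB")
    for (rep in 1:5) {
        set.seed(300 + rep)
        a <- sample(c(-1, 1), 30, replace = TRUE) * runif(30)
        b <- sample(c(-1, 1), 30, replace = TRUE) * runif(30)
        res <- classifyBinChanges(fixtureProfile(a), fixtureProfile(b))
        expect_equal(unname(res$counts["AtoB"]), sum(a > 0 & b < 0))
        expect_equal(unname(res$counts["BtoA"]), sum(a < 0 & b > 0))
    }
    expect_error(classifyBinChanges(p, fixtureProfile(c(1, -1))), "grid")
})

test_that("insulation is flat on uniform matrices and dips at block joins", {
    n <- 20
    uni <- fixtureContactMatrix(matrix(5, n, n), balanced = TRUE)
    ins <- insulationScore(uni, window = 3)
    inner <- ins[4:(n - 3)]
    expect_true(all(abs(inner) < 1e-12))
    expect_true(all(is.na(ins[1:3])))
    expect_true(all(is.na(ins[(n - 2):n])))
    # two diagonal blocks with no cross-block contact: the dip sits at the
    # block join and border calling lands on its first bin
    blk <- matrix(0, n, n)
    blk[1:10, 1:10] <- 5; blk[11:20, 11:20] <- 5
    cmB <- fixtureContactMatrix(blk, balanced = TRUE)
    insB <- insulationScore(cmB, window = 3)
    expect_equal(which.min(insB), 10)
    expect_true(all(insB[c(10, 11)] < insB[-c(10, 11)], na.rm = TRUE))
    # direct-evaluation oracle away from the join: bin 9 sees 3 of 9 cells
    # filled at 5, so raw = 5/3 and the score is log2((5/3)/mean(raw))
    up <- 6:8; dn <- 10:12
    raws <- vapply(4:(n - 3), function(i)
        mean(blk[(i - 3):(i - 1), (i + 1):(i + 3)]), numeric(1))
    expect_equal(insB[9], log2((5 / 3) / mean(raws)))
    part <- callBorders(cmB, window = 3, prominenceMin = 0.5)
    expect_equal(borders(part), 10L)
})

test_that("border calling anchors strength at 10 and skips monotone vectors", {
    n <- 40
    cmDummy <- fixtureContactMatrix(matrix(1, n, n), balanced = TRUE)
    mono <- seq(0, 1, length.out = n)
    part <- callBorders(cmDummy, insulationVector = mono)
    expect_length(borders(part), 0)
    dip <- rep(0, n); dip[20] <- -2
    part <- callBorders(cmDummy, insulationVector = dip)
    expect_equal(borders(part), 20L)
    expect_equal(borderStrength(part), 10)
    expect_equal(borderProminence(part), 2)
    # masked bins never become borders
    sim <- defaultSim()
    cm <- simulateHic(sim$genome, sim$truth, "untreated", resolution = 4e4,
                      seed = 4)
    m <- contactMap(cm)
    kill <- 137
    m[kill, ] <- 0; m[, kill] <- 0
    bal <- balanceMatrix(fixtureContactMatrix(m, resolution = 4e4))
    expect_true(binMask(bal)[kill])
    part <- callBorders(bal)
    expect_false(kill %in% borders(part))
})

test_that("border matching and the conserved fraction follow the tolerance", {
    p1 <- fixturePartition(c(20, 50, 80), nBins = 100)
    same <- matchBorders(list(a = p1, b = p1, c = p1))
    expect_equal(same$conservedFraction, 1)
    p2 <- fixturePartition(c(20, 50, 80) + 3, nBins = 100)
    shifted <- matchBorders(list(a = p1, b = p2), tol = 2)
    expect_equal(shifted$conservedFraction, 0)
    within <- matchBorders(list(a = p1,
                                b = fixturePartition(c(21, 49, 80),
                                                     nBins = 100)), tol = 2)
    expect_equal(within$conservedFraction, 1)
    # brute-force oracle on random border sets
    for (rep in 1:6) {
        set.seed(400 + rep)
        mk <- function() sort(sample(seq(5, 495, by = 6),
                                     sample(3:15, 1)))
        b1 <- mk(); b2 <- mk()
        res <- matchBorders(list(a = fixturePartition(b1, 500),
                                 b = fixturePartition(b2, 500)), tol = 2)
        # single-linkage clusters over the pooled borders
        pooled <- sort(unique(c(b1, b2)))
        grp <- cumsum(c(TRUE, diff(pooled) > 2))
        oracle <- vapply(split(pooled, grp), function(cl)
            any(cl %in% b1) && any(cl %in% b2), logical(1))
        expect_equal(res$conservedFraction, mean(oracle))
    }
})

test_that("border peak occupancy matches a quadratic intersection oracle", {
    part <- fixturePartition(c(10, 30, 60), nBins = 100, resolution = 1e3)
    none <- borderPeakOccupancy(part,
                                fixturePeaks(integer(0), integer(0), len = 1e5),
                                chromLength = 1e5)
    expect_equal(unname(none$histogram["0"]), 3)
    onePk <- fixturePeaks(9100, 9200, len = 1e5)
    one <- borderPeakOccupancy(part, onePk, chromLength = 1e5)
    expect_equal(one$perBorder, c(1L, 0L, 0L))
    for (rep in 1:5) {
        set.seed(500 + rep)
        st <- sort(sample(seq(1, 9.9e4, by = 137), 25))
        pk <- fixturePeaks(st, st + 99, len = 1e5)
        occ <- borderPeakOccupancy(part, pk, chromLength = 1e5)
        iv <- borderIntervals(part, 1e5)
        oracle <- vapply(seq_along(iv), function(i)
            sum(st <= end(iv)[i] & st + 99 >= start(iv)[i]), integer(1))
        expect_equal(occ$perBorder, oracle)
    }
})
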