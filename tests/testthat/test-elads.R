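# Gap-merge segmentation of sites into domains and interval algebra.

test_that("gap merging clusters peaks and enforces the site threshold", {
    expect_length(domains(callELads(fixturePeaks(integer(0), integer(0)))), 0)
    # peaks [0,1k), [50k,51k), [500k,501k) in 0-based half-open terms
    pk <- fixturePeaks(starts = c(1, 50001, 500001),
                       ends = c(1000, 51000, 501000))
    el <- callELads(pk, maxGap = 1e5, minSites = 2)
    dom <- domains(el)
    expect_length(dom, 1)
    expect_equal(start(dom), 1)
    expect_equal(end(dom), 51000)
    expect_equal(mcols(dom)$siteCount, 2)
    # an isolated peak below the threshold is discarded
    one <- fixturePeaks(starts = 1, ends = 1000)
    expect_length(domains(callELads(one, minSites = 2)), 0)
})

test_that("clustering matches a brute-force all-pairs gap oracle", {
    bruteClusters <- function(st, en, maxGap) {
        grp <- integer(length(st)); grp[1] <- 1
        for (i in seq_along(st)[-1])
            grp[i] <- if (st[i] - en[i - 1] - 1 <= maxGap) grp[i - 1]
                      else grp[i - 1] + 1
        grp
    }
    for (rep in 1:8) {
        set.seed(100 + rep)
        n <- sample(3:15, 1)
        st <- sort(sample(seq(1, 9e5, by = 1500), n))
        en <- st + sample(500:1400, n, replace = TRUE)
        maxGap <- sample(c(2e3, 1e4, 5e4), 1)
        minSites <- sample(1:3, 1)
        el <- callELads(fixturePeaks(st, en), maxGap = maxGap,
                        minSites = minSites)
        grp <- bruteClusters(st, en, maxGap)
        keep <- table(grp) >= minSites
        expStart <- as.numeric(tapply(st, grp, min)[keep])
        expEnd <- as.numeric(tapply(en, grp, max)[keep])
        expect_equal(start(domains(el)), expStart)
        expect_equal(end(domains(el)), expEnd)
        expect_equal(mcols(domains(el))$siteCount,
                     as.integer(table(grp)[keep]), ignore_attr = TRUE)
    }
})

test_that("increasing maxGap never raises cluster count nor lowers coverage", {
    set.seed(5)
    st <- sort(sample(seq(1, 9e5, by = 1200), 60))
    pk <- fixturePeaks(st, st + 999)
    gm <- fixtureGenome(1e6)
    prev <- NULL
    # the monotonicity holds at the clustering level (minSites = 1); the
    # site-count filter applied afterwards can break it by promoting merged
    # singletons
    for (g in c(2e3, 1e4, 5e4, 2e5)) {
        s <- domainSummary(callELads(pk, maxGap = g, minSites = 1), gm)
        if (!is.null(prev)) {
            expect_lte(s["nDomains"], prev["nDomains"])
            expect_gte(s["coverage"], prev["coverage"] - 1e-12)
        }
        prev <- s
    }
})

test_that("re-calling on a domain's own member peaks is idempotent", {
    set.seed(9)
    st <- sort(sample(seq(1, 9e5, by = 1200), 50))
    pk <- fixturePeaks(st, st + 999)
    el <- callELads(pk, maxGap = 3e4, minSites = 3)
    inDom <- IRanges::overlapsAny(peaks(pk), domains(el))
    pk2 <- new("PeakSet", condition = "test", granges = peaks(pk)[inDom])
    el2 <- callELads(pk2, maxGap = 3e4, minSites = 3)
    expect_equal(as.data.frame(domains(el2)), as.data.frame(domains(el)))
})

test_that("domain summaries use exact arithmetic", {
    gm1 <- fixtureGenome(1e6)
    expect_equal(domainSummary(fixtureELads(integer(0), integer(0)), gm1),
                 c(nDomains = 0, meanSize = 0, coverage = 0))
    full <- fixtureELads(1, 1e6, len = 1e6)
    expect_equal(domainSummary(full, gm1),
                 c(nDomains = 1, meanSize = 1e6, coverage = 1))
    gm2 <- fixtureGenome(2e6)
    two <- fixtureELads(c(1, 1e6), c(2e5, 1e6 + 4e5 - 1), len = 2e6)
    expect_equal(domainSummary(two, gm2),
                 c(nDomains = 2, meanSize = 3e5, coverage = 0.3))
})

test_that("base-pair overlap statistics are exact", {
    a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
    identical <- intervalOverlapStats(a, a)
    expect_equal(identical$fractionAinB, 1)
    expect_equal(identical$jaccard, 1)
    b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 300))
    disjoint <- intervalOverlapStats(a, b)
    expect_equal(disjoint$fractionAinB, 0)
    expect_equal(disjoint$jaccard, 0)
    # A = [0,100), B = [50,150) in 0-based half-open terms
    a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
    b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150))
    ov <- intervalOverlapStats(a, b)
    expect_equal(ov$fractionAinB, 0.5)
    expect_equal(ov$jaccard, 1 / 3)
    expect_true(ov$overlapFlags)
})

test_that("maintained/new/lost flags match a quadratic overlap oracle", {
    idSets <- function(starts, ends) fixtureELads(starts, ends)
    s1 <- fixtureELads(c(1e3, 5e4), c(2e3, 6e4))
    cmp <- compareELadSets(list(c1 = s1, c2 = s1, c3 = s1))
    for (cond in names(cmp)) {
        expect_length(cmp[[cond]]$maintained, 2)
        expect_length(cmp[[cond]]$new, 0)
        expect_length(cmp[[cond]]$lost, 0)
    }
    s2 <- fixtureELads(c(1e3, 5e4, 9e5), c(2e3, 6e4, 9.1e5))
    cmp <- compareELadSets(list(c1 = s1, c2 = s2))
    expect_length(cmp$c2$new, 1)
    expect_equal(start(cmp$c2$new), 9e5)
    expect_length(cmp$c1$lost, 0)
    for (rep in 1:6) {
        set.seed(200 + rep)
        mk <- function() {
            n <- sample(2:10, 1)
            st <- sort(sample(seq(1, 9.5e5, by = 3e4), n))
            fixtureELads(st, st + sample(2e3:2e4, n, replace = TRUE))
        }
        sets <- list(c1 = mk(), c2 = mk(), c3 = mk())
        cmp <- compareELadSets(sets)
        grs <- lapply(sets, domains)
        for (t in seq_along(grs)) {
            gr <- grs[[t]]
            oracleMaint <- vapply(seq_along(gr), function(i) {
                all(vapply(seq_len(t - 1), function(u)
                    any(start(gr)[i] <= end(grs[[u]]) &
                        end(gr)[i] >= start(grs[[u]])), logical(1)))
            }, logical(1))
            oracleLost <- vapply(seq_along(gr), function(i) {
                later <- setdiff(seq_along(grs), seq_len(t))
                !all(vapply(later, function(u)
                    any(start(gr)[i] <= end(grs[[u]]) &
                        end(gr)[i] >= start(grs[[u]])), logical(1)))
            }, logical(1))
            nm <- names(sets)[t]
            expect_equal(length(cmp[[nm]]$maintained), sum(oracleMaint))
            expect_equal(length(cmp[[nm]]$new), sum(!oracleMaint))
            expect_equal(length(cmp[[nm]]$lost), sum(oracleLost))
        }
    }
})

test_that("unsorted or overlapping peak input is normalized with a warning", {
    gr <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(5e4, 1, 5.05e4), c(5.1e4, 1000, 5.2e4)))
    expect_warning(el <- callELads(gr, maxGap = 1e4, minSites = 1),
                   "normaliz")
    dom <- domains(el)
    expect_equal(start(dom), c(1, 5e4))
    expect_equal(end(dom), c(1000, 5.2e4))
})
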