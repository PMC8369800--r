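test_that("aggregateTADPairs conserves totals and scales with TAD size", {
    sim <- simulateContactMap(simConfig(nBins = 120L, depth = 2e5,
                                        seed = 1))
    cm <- mergeReplicates(sim$matrices)
    ts <- tadSet(trueBoundaries(sim$truth), 120L)
    agg <- aggregateTADPairs(cm, ts)
    m <- counts(cm)
    expect_equal(agg$total, sum(m[upper.tri(m, diag = TRUE)]))
    expect_equal(sum(agg$observed[upper.tri(agg$observed, diag = TRUE)]),
                 agg$total)
    ## single whole-chromosome TAD: one cell = total intra count
    one <- aggregateTADPairs(cm, tadSet(integer(), 120L))
    expect_equal(dim(one$observed), c(1L, 1L))
    expect_equal(one$observed[1, 1], agg$total)
    ## uniform matrix: off-diagonal observed proportional to |p| * |q|
    u <- contactMatrix(matrix(4, 120, 120))
    aggU <- aggregateTADPairs(u, ts)
    d <- domains(ts)
    sz <- d[, 2] - d[, 1] + 1
    expect_equal(aggU$observed[1, 3], 4 * sz[1] * sz[3])
})

test_that("callSignificant output respects its invariants", {
    sim <- simulateContactMap(simConfig(nBins = 150L, depth = 3e5,
                                        seed = 2))
    cm <- mergeReplicates(sim$matrices)
    ts <- tadSet(trueBoundaries(sim$truth), 150L)
    calls <- callSignificant(aggregateTADPairs(cm, ts))
    expect_true(all(calls$p >= 0 & calls$p <= 1))
    expect_true(all(calls$fdr >= 0 & calls$fdr <= 1))
    expect_true(all(calls$fdr >= calls$p))
    expect_equal(calls$oe, calls$observed / calls$expected)
    expect_true(all(calls$distance >= 0))
    expect_true(all(calls$significant ==
                    (is.finite(calls$oe) & calls$fdr < 0.01 &
                     calls$oe >= 10)))
    nT <- nrow(domains(ts))
    expect_equal(nrow(calls), nT * (nT - 1) / 2)
})

test_that("a strongly boosted TAD pair is called; oe >= 10 filters", {
    sim <- simulateContactMap(simConfig(nBins = 200L, depth = 5e5, seed = 3,
                                        tadBoost = 1, loopBoost = 1,
                                        compartmentAmplitude = 0),
                              nLoops = 0L)
    cm <- mergeReplicates(sim$matrices)
    ts <- tadSet(trueBoundaries(sim$truth), 200L)
    d <- domains(ts)
    m <- counts(cm)
    p <- 2L; q <- nrow(d) - 2L
    ia <- d[p, 1]:d[p, 2]; ib <- d[q, 1]:d[q, 2]
    set.seed(99)
    m[ia, ib] <- rpois(length(ia) * length(ib),
                       20 * pmax(mean(m[ia, ib]), 1e-3))
    m[ib, ia] <- t(m[ia, ib])
    calls <- callSignificant(aggregateTADPairs(contactMatrix(m), ts))
    hit <- calls[calls$tadA == p & calls$tadB == q, ]
    expect_true(hit$significant)
    expect_gt(hit$oe, 10)
    ## everything else stays uncalled
    expect_equal(sum(calls$significant), 1L)
})

test_that("classifyBySignal applies deciles with stated precedence", {
    n <- 100L
    v <- seq_len(n)   # strictly increasing signal, deciles unambiguous
    track <- signalTrack(v, binSize = 100)
    mkCall <- function(a, b) data.frame(
        tadA = 1L, tadB = 2L,
        startA = (a - 1) * 100, endA = a * 100,
        startB = (b - 1) * 100, endB = b * 100,
        observed = 1, expected = 1, oe = 1, p = 0.5, fdr = 0.5,
        significant = FALSE, distance = abs(b - a) * 100, class = "none")
    calls <- rbind(mkCall(95, 99),   # both top decile
                   mkCall(2, 5),     # both bottom decile
                   mkCall(50, 55),   # middle
                   mkCall(95, 5))    # mixed top/bottom -> not both-top
    out <- classifyBySignal(calls, track, topQ = 0.10, seed = 1)
    expect_identical(out$class[1], "enriched")
    expect_identical(out$class[2], "absent")
    expect_true(out$class[3] %in% c("random", "none"))
    expect_false(out$class[4] %in% c("enriched", "absent"))
    ## deterministic random set under the seed
    out2 <- classifyBySignal(calls, track, topQ = 0.10, seed = 1)
    expect_identical(out$class, out2$class)
    expect_error(classifyBySignal(calls, signalTrack(rep(1, n))),
                 "non-informative")
})

test_that("distanceDistribution compares classes pairwise", {
    calls <- data.frame(
        distance = c(1e6, 2e6, 3e6, 50e6, 60e6, 70e6),
        class = c(rep("enriched", 3), rep("absent", 3)))
    dd <- distanceDistribution(calls, c("enriched", "absent"))
    expect_equal(dd$p["enriched", "absent"], dd$p["absent", "enriched"])
    expect_lt(dd$p["enriched", "absent"], 0.2)
    ident <- distanceDistribution(
        data.frame(distance = rep(c(1, 2, 3), 2),
                   class = rep(c("enriched", "absent"), each = 3)),
        c("enriched", "absent"))
    expect_equal(ident$p["enriched", "absent"], 1)
})

test_that("apa satisfies its analytic and symmetry contracts", {
    ## all-ones O/E window: grid of ones, scores 1
    m <- matrix(1, 60, 60)
    res <- apa(oeMatrix(m), cbind(20L, 45L), k = 5L)
    expect_equal(res$grid, matrix(1, 11, 11))
    expect_equal(res$centerScore, 1)
    expect_equal(res$cornerMean, 1)
    expect_equal(res$n, 1L)
    ## order invariance
    sim <- simulateContactMap(simConfig(nBins = 200L, depth = 4e5,
                                        seed = 5))
    oe <- oeTransform(iceBalance(mergeReplicates(sim$matrices)))
    an <- loopAnchors(sim$truth)
    a1 <- apa(oe, an)
    a2 <- apa(oe, an[rev(seq_len(nrow(an))), ])
    expect_equal(a1$grid, a2$grid)
    ## edge / diagonal filtering with error when nothing is left
    expect_error(apa(oeMatrix(m), cbind(2L, 5L), k = 5L), "eligible")
    r <- apa(oeMatrix(m), rbind(c(2L, 5L), c(20L, 45L)), k = 5L)
    expect_equal(r$nFiltered, 1L)
})

test_that("apa center enrichment reflects the planted loop boost", {
    sim <- simulateContactMap(simConfig(nBins = 200L, depth = 6e5, seed = 6,
                                        loopBoost = 3))
    oe <- oeTransform(iceBalance(mergeReplicates(sim$matrices)))
    res <- apa(oe, loopAnchors(sim$truth))
    expect_gt(res$centerScore / res$cornerMean, 1.5)
})
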