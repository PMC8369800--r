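test_that("binSignal matches its analytic cases", {
    ## constant matrix: every interior diamond mean equals the constant
    cm <- contactMatrix(matrix(3, 30, 30))
    s <- binSignal(cm, window = 5L)
    expect_equal(s, rep(3, 29))
    ## two perfect blocks: zero cross-block contact => signal 0 at the split
    m <- matrix(0, 20, 20)
    m[1:10, 1:10] <- 5; m[11:20, 11:20] <- 5
    s2 <- binSignal(contactMatrix(m), window = 3L)
    expect_equal(s2[10], 0)
    expect_true(all(s2[c(5, 15)] > 0))
    expect_error(binSignal(cm, window = 50L), "window")
})

test_that("callTADs recovers planted boundaries and tiles the chromosome", {
    sim <- simulateContactMap(simConfig(nBins = 300L, depth = 6e5,
                                        seed = 8, tadBoost = 3))
    bal <- iceBalance(mergeReplicates(sim$matrices))
    ts <- callTADs(bal)
    d <- domains(ts)
    expect_equal(unname(d[1, 1]), 1L)
    expect_equal(unname(d[nrow(d), 2]), 300L)
    expect_true(all(d[-1, 1] == d[-nrow(d), 2] + 1L))
    f1 <- boundaryF1(boundaries(ts), trueBoundaries(sim$truth))
    expect_gt(f1$f1, 0.9)
})

test_that("callTADs on a boost-free matrix yields few spurious boundaries", {
    spur <- sapply(1:5, function(s) {
        sim <- simulateContactMap(simConfig(nBins = 200L, depth = 4e5,
                                            seed = s, tadBoost = 1,
                                            loopBoost = 1), nLoops = 0L)
        length(boundaries(callTADs(iceBalance(mergeReplicates(
            sim$matrices)))))
    })
    ## a ~1% per-bin false boundary rate, versus the ~24 true boundaries
    ## recovered on boosted matrices of the same size
    expect_lte(mean(spur), 3)
    expect_true(all(spur <= 5))
})

test_that("directionIndex counts flanking contacts with edge truncation", {
    m <- matrix(1, 20, 20)
    di <- directionIndex(list(contactMatrix(m)), span = 7L)[[1]]
    expect_equal(di$up[1], 0)         # nothing upstream of bin 1
    expect_equal(di$down[20], 0)
    expect_equal(di$up[10], 7)        # interior: span cells of 1
    expect_equal(di$down[10], 7)
    ## bin left of a strong boundary: up >> down
    m2 <- matrix(0, 20, 20)
    m2[1:10, 1:10] <- 50; m2[11:20, 11:20] <- 50
    di2 <- directionIndex(list(contactMatrix(m2)), span = 7L)[[1]]
    expect_gt(di2$up[10], 10 * max(1, di2$down[10]))
})

test_that("testBoundaryChange flags a planted deletion and needs replicates", {
    ev <- data.frame(timepoint = "2", type = "fusion", n = 1L)
    tc <- simulateTimecourse(simConfig(nBins = 300L, depth = 6e5,
                                       seed = 17, tadBoost = 3),
                             bareSchedule(c("0", "2"), tadEvents = ev),
                             nLoops = 0L)
    lostB <- truthParams(tc[["2"]]$truth)$tadEvents$lost[1]
    t0s <- callTADs(iceBalance(mergeReplicates(tc[["0"]]$matrices)))
    t2s <- callTADs(iceBalance(mergeReplicates(tc[["2"]]$matrices)))
    ch <- testBoundaryChange(directionIndex(tc[["2"]]$matrices),
                             directionIndex(tc[["0"]]$matrices),
                             boundaries(t0s), boundaries(t2s),
                             timepoint = "2")
    hit <- ch[abs(ch$boundary - lostB) <= 1, ]
    expect_true(any(hit$direction == "lost" & hit$fdr < 0.05))
    expect_error(testBoundaryChange(directionIndex(tc[["2"]]$matrices)[1],
                                    directionIndex(tc[["0"]]$matrices),
                                    boundaries(t0s), boundaries(t2s)),
                 "two replicates")
    empty <- testBoundaryChange(directionIndex(tc[["2"]]$matrices),
                                directionIndex(tc[["0"]]$matrices),
                                integer(), integer())
    expect_equal(nrow(empty), 0L)
})

test_that("classifyReorganization resolves the hand-constructed cases", {
    ref <- tadSet(c(50L, 100L, 150L), 200L)
    ## fusion: loss at 100
    alt <- tadSet(c(50L, 150L), 200L)
    ch <- data.frame(boundary = c(50L, 100L, 150L),
                     direction = c("stable", "lost", "stable"),
                     p = 0, fdr = 0, timepoint = "2")
    ev <- classifyReorganization(ref, alt, ch)
    expect_equal(nrow(ev$events), 1L)
    expect_identical(ev$events$type, "fusion")
    expect_equal(ev$events$lost, 100L)
    expect_equal(ev$unchanged, 2L)
    ## shifting: loss 100 + gain 102 within tolerance 2
    alt2 <- tadSet(c(50L, 102L, 150L), 200L)
    ch2 <- data.frame(boundary = c(50L, 100L, 102L, 150L),
                      direction = c("stable", "lost", "gained", "stable"),
                      p = 0, fdr = 0, timepoint = "2")
    ev2 <- classifyReorganization(ref, alt2, ch2)
    expect_identical(ev2$events$type, "shifting")
    expect_equal(ev2$events$gained, 102L)
    ## separation: pure gain
    alt3 <- tadSet(c(50L, 100L, 125L, 150L), 200L)
    ch3 <- data.frame(boundary = 125L, direction = "gained",
                      p = 0, fdr = 0, timepoint = "2")
    ev3 <- classifyReorganization(ref, alt3, ch3)
    expect_identical(ev3$events$type, "separation")
    ## every significant change lands in exactly one event
    ch4 <- data.frame(boundary = c(100L, 102L, 125L),
                      direction = c("lost", "gained", "gained"),
                      p = 0, fdr = 0, timepoint = "2")
    alt4 <- tadSet(c(50L, 102L, 125L, 150L), 200L)
    ev4 <- classifyReorganization(ref, alt4, ch4)
    expect_equal(nrow(ev4$events), 2L)
    expect_setequal(ev4$events$type, c("shifting", "separation"))
    expect_error(classifyReorganization(ref, alt,
        data.frame(boundary = 999L, direction = "lost", p = 0, fdr = 0,
                   timepoint = "2")),
        "absent")
})

test_that("resize_bilinear matches reference bilinear interpolation", {
    set.seed(4)
    a <- matrix(rnorm(15 * 15), 15, 15)
    sub <- a + t(a)                      # symmetric, like a contact map
    target <- 40L
    xi <- seq(1, 15, length.out = target)
    ref <- matrix(pracma::interp2(1:15, 1:15, sub,
                                  rep(xi, each = target),
                                  rep(xi, times = target)),
                  target, target, byrow = TRUE)
    expect_equal(HiCflux:::resize_bilinear(sub, target), ref)
    ## fixed points: corners are preserved
    rs <- HiCflux:::resize_bilinear(sub, 29L)
    expect_equal(rs[1, 1], sub[1, 1])
    expect_equal(rs[29, 29], sub[15, 15])
    expect_equal(rs, t(rs))
})

test_that("ata recovers the intra-TAD boost on a common grid", {
    sim <- simulateContactMap(simConfig(nBins = 300L, depth = 6e5,
                                        seed = 9, tadBoost = 3))
    oe <- oeTransform(iceBalance(mergeReplicates(sim$matrices)))
    ts <- tadSet(trueBoundaries(sim$truth), 300L)
    at <- ata(oe, ts)
    expect_equal(dim(at$grid), c(100L, 100L))
    expect_gt(at$bodyMean / at$flankMean, 1.5)
    expect_gt(at$nTads, 0)
    ## single-TAD input equals its own resized submatrix
    one <- ata(oe, ts, select = 3L)
    d <- domains(ts)[3, ]
    L <- d[2] - d[1] + 1L
    fl <- round(0.5 * L)
    sub <- counts(oe)[(d[1] - fl):(d[2] + fl), (d[1] - fl):(d[2] + fl)]
    if (anyNA(sub)) sub[is.na(sub)] <- mean(sub, na.rm = TRUE)
    expect_equal(one$grid, HiCflux:::resize_bilinear(sub, 100L))
    ## label-filter selector: logical vector accepted
    sel <- rep(FALSE, nrow(domains(ts))); sel[2:4] <- TRUE
    expect_equal(ata(oe, ts, select = sel)$nTads,
                 sum((domains(ts)[sel, 2] - domains(ts)[sel, 1] + 1) > 3))
})

test_that("boundaryF1 matches greedily within tolerance", {
    r <- boundaryF1(c(10L, 20L, 31L), c(10L, 21L, 50L), tol = 1L)
    expect_equal(r$nMatched, 2L)
    expect_equal(r$precision, 2 / 3)
    expect_equal(r$recall, 2 / 3)
    expect_equal(r$f1, 2 / 3)
    expect_equal(boundaryF1(integer(), c(5L))$f1, 0)
})
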