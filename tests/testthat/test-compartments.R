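## one moderately sized simulated chromosome shared across this file
simC <- simulateContactMap(simConfig(nBins = 300L, depth = 6e5, seed = 21))
oeC <- oeTransform(iceBalance(mergeReplicates(simC$matrices)))
truthC <- simC$truth
orientC <- simulateSignalTrack(trueProfile(truthC), enrichment = 1,
                               noiseSd = 0.2, seed = 21)

test_that("computePC1 recovers the planted profile with A oriented up", {
    prof <- computePC1(oeC, orientC)
    expect_s4_class(prof, "CompartmentProfile")
    cc <- cor(pc1(prof), trueProfile(truthC), use = "complete.obs")
    expect_gt(cc, 0.9)       # sign already resolved by the orientation
    ## 99th percentile scaling
    expect_equal(unname(quantile(abs(pc1(prof)), 0.99, na.rm = TRUE)), 1)
    ## orientation flip inverts the profile deterministically
    flip <- signalTrack(max(trackValues(orientC)) - trackValues(orientC))
    prof2 <- computePC1(oeC, flip)
    expect_equal(pc1(prof2), -pc1(prof))
})

test_that("TAD-level smoothing denoises the eigenvector", {
    prof <- computePC1(oeC, orientC)
    sm <- smoothByTADs(prof, tadSet(trueBoundaries(truthC), nbins(oeC)))
    e <- trueProfile(truthC)
    mseRaw <- mean((zscore(pc1(prof)) - zscore(e))^2, na.rm = TRUE)
    mseSm <- mean((zscore(pc1(sm)) - zscore(e))^2, na.rm = TRUE)
    expect_lt(mseSm, mseRaw)
    ## smoothing is idempotent per TAD: all bins of a domain share a value
    d <- domains(tadSet(trueBoundaries(truthC), nbins(oeC)))
    for (t in c(1, nrow(d))) {
        v <- pc1(sm)[d[t, 1]:d[t, 2]]
        v <- v[!is.na(v)]               # masked bins stay NA
        expect_gt(length(v), 0)
        expect_equal(max(v) - min(v), 0)
    }
})

test_that("perBinStrength equals 4 on the analytic checkerboard", {
    n <- 40
    e <- rep(c(1, -1), each = 4, length.out = n)
    m <- matrix(0.5, n, n)
    m[outer(e, e) > 0] <- 2
    strength <- perBinStrength(oeMatrix(m), profileFromValues(e))
    expect_equal(strength, rep(4, n))
})

test_that("classifyStrengthChange partitions bins by fold", {
    s0 <- c(1, 1, 1, 1, NA)
    sT <- c(2.5, 0.4, 1.2, 1, 2)
    cl <- classifyStrengthChange(sT, s0, fold = 2)
    expect_identical(cl$class[1:4],
                     c("strengthened", "weakened", "unchanged", "unchanged"))
    expect_true(is.na(cl$class[5]))
    expect_equal(sum(cl$proportions), 1)
})

test_that("saddle grid is symmetric and scores the planted compartments", {
    prof <- computePC1(oeC, orientC)
    sd1 <- saddle(oeC, prof, n = 30)
    expect_identical(sd1$grid, t(sd1$grid))
    expect_gt(sd1$score, 1.2)
    ## analytic two-level checkerboard: same 1.6 / cross 0.4 => score 4
    n <- 200
    e <- rep(c(1, -1), each = 10, length.out = n)
    m <- matrix(0.4, n, n); m[outer(e, e) > 0] <- 1.6
    sd2 <- saddle(oeMatrix(m), e, n = 20, qrange = c(0, 1))
    expect_equal(sd2$score, 4)
    expect_error(saddle(oeC, prof, n = 1e5), "fewer")
})

test_that("interactionsByPC1Range averages disjoint PC1 groups", {
    n <- 30
    e <- c(rep(-1, 10), rep(0.2, 10), rep(1, 10))
    m <- outer(e, e) + 2
    grid <- interactionsByPC1Range(oeMatrix(m), e,
        list(low = c(-2, -0.5), mid = c(-0.5, 0.5), high = c(0.5, 2)))
    expect_equal(grid["low", "high"], mean((outer(e[1:10], e[21:30]) + 2)))
    expect_identical(grid, t(grid))
    expect_error(interactionsByPC1Range(oeMatrix(m), e,
        list(a = c(-1, 0.5), b = c(0, 1))), "disjoint")
})

test_that("homogeneity is 1/CV^2 with the sample variance", {
    expect_equal(homogeneity(c(1, 2, 3)), 4)
    expect_equal(homogeneity(c(5, 5, 5)), Inf)
    v <- rlnorm(50)
    expect_equal(homogeneity(v * 100), homogeneity(v))
    expect_error(homogeneity(numeric(0)))
    expect_error(homogeneity(c(-2, -3)))
})

test_that("sameTypeGroupMeans feeds homogeneity with group-pair means", {
    prof <- smoothByTADs(computePC1(oeC, orientC),
                         tadSet(trueBoundaries(truthC), nbins(oeC)))
    gm <- sameTypeGroupMeans(oeC, prof, "A", nGroups = 5)
    expect_length(gm, 5 * 6 / 2)
    expect_true(all(is.finite(gm)))
    expect_gt(homogeneity(gm), 0)
    expect_error(sameTypeGroupMeans(oeC, prof, "A", nGroups = 1000),
                 "too few")
})

test_that("compartmentRegions are maximal label runs", {
    prof <- profileFromValues(c(1, 1, -1, -1, -1, 2), binSize = 10)
    gr <- compartmentRegions(prof)
    expect_equal(length(gr), 3L)
    expect_identical(gr$label, c("A", "B", "A"))
    expect_equal(GenomicRanges::start(gr), c(1, 21, 51))
    expect_equal(GenomicRanges::end(gr), c(20, 50, 60))
    st <- regionSizeStats(gr, "A")
    expect_equal(st$meanSize, 15)
    expect_equal(st$totalLength, 30)
})

test_that("classifySwitch labels constant and switching trajectories", {
    ## hand-built trajectories over 0 / t / withdrawal+1 treated tp
    mk <- function(labels, tp) {
        e <- ifelse(labels == "A", 1, -1)
        profileFromValues(e, timepoint = tp)
    }
    labs <- rbind(c("A", "A", "A", "A"),     # constant A
                  c("B", "A", "A", "B"),     # early recoverable
                  c("B", "B", "A", "A"),     # late irrecoverable
                  c("A", "A", "A", "A"))
    profs <- lapply(1:4, function(k) mk(labs[, k], c("0", "2", "10",
                                                     "withdrawal")[k]))
    names(profs) <- c("0", "2", "10", "withdrawal")
    sw <- classifySwitch(profs)
    r <- sw$regions
    expect_equal(nrow(r), 4L)
    expect_identical(r$class, c("constant A", "switch", "switch",
                                "constant A"))
    expect_identical(r$subtype[2], "early-affected, recoverable")
    expect_identical(r$subtype[3], "late-affected, irrecoverable")
    expect_equal(sum(sw$proportions), 1)
    expect_error(classifySwitch(profs[1:2]), "withdrawal|named")
})

test_that("classifySwitch on a full simulated stack recovers all labels", {
    ## complete route: simulate -> balance -> O/E -> PC1 -> smooth -> classify
    cfg <- simConfig(nBins = 400L, seed = 4)
    tc <- simulateTimecourse(cfg, perturbationSchedule(), nLoops = 4L)
    orient <- simulateSignalTrack(truthParams(tc[["0"]]$truth)$baselineProfile,
                                  enrichment = 1, noiseSd = 0.2, seed = 4)
    profs <- lapply(names(tc), function(tp) {
        oe <- oeTransform(iceBalance(mergeReplicates(tc[[tp]]$matrices)))
        smoothByTADs(computePC1(oe, orient, timepoint = tp),
                     tadSet(trueBoundaries(tc[[tp]]$truth), nbins(oe)))
    })
    names(profs) <- names(tc)
    sw <- classifySwitch(profs)
    got <- sw$regions$subtype[sw$regions$class == "switch"]
    expect_setequal(unique(got),
                    c("early-affected, recoverable",
                      "early-affected, irrecoverable",
                      "late-affected, recoverable",
                      "late-affected, irrecoverable"))
    expect_true(any(grepl("constant", sw$regions$class)))
    expect_true(is.finite(sw$lowPC1Enrichment$p))
})
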