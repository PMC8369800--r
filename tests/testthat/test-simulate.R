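test_that("simulateContactMap is deterministic under a fixed seed", {
    cfg <- simConfig(nBins = 120L, depth = 2e5, seed = 3)
    a <- simulateContactMap(cfg)
    b <- simulateContactMap(cfg)
    expect_identical(counts(a$matrices[[1]]), counts(b$matrices[[1]]))
    expect_identical(trueProfile(a$truth), trueProfile(b$truth))
    expect_identical(trueBoundaries(a$truth), trueBoundaries(b$truth))
    ## and changes with the seed
    d <- simulateContactMap(simConfig(nBins = 120L, depth = 2e5, seed = 4))
    expect_false(identical(counts(a$matrices[[1]]),
                           counts(d$matrices[[1]])))
})

test_that("simulated matrices are symmetric non-negative counts", {
    sim <- simulateContactMap(simConfig(nBins = 100L, depth = 1e5,
                                        seed = 1))
    for (cm in sim$matrices) {
        m <- counts(cm)
        expect_identical(m, t(m))
        expect_true(all(m >= 0))
        expect_true(all(m == round(m)))
    }
    expect_length(sim$matrices, 2L)
})

test_that("replicates share one intensity but differ in noise", {
    sim <- simulateContactMap(simConfig(nBins = 100L, depth = 2e5,
                                        seed = 2))
    m1 <- counts(sim$matrices[[1]]); m2 <- counts(sim$matrices[[2]])
    expect_false(identical(m1, m2))
    ## totals near the configured depth (Poisson, so within ~5 sd)
    tot <- sum(m1[upper.tri(m1, diag = TRUE)])
    expect_lt(abs(tot - 2e5), 5 * sqrt(2e5))
})

test_that("planted structure matches its invariants", {
    sim <- simulateContactMap(simConfig(nBins = 300L, seed = 7))
    tr <- sim$truth
    b <- trueBoundaries(tr)
    ## TAD lengths 8..16 bins (last may be shorter)
    lens <- diff(c(0L, b))
    expect_true(all(lens >= 8 & lens <= 16))
    ## compartment segments are unions of TADs: every profile step sits on
    ## a TAD boundary
    e <- trueProfile(tr)
    steps <- which(diff(e) != 0)
    expect_true(all(steps %in% b))
    expect_true(all(abs(e) <= 1))
    ## anchors: i < j, inside margins
    an <- loopAnchors(tr)
    expect_true(all(an[, 1] < an[, 2]))
    expect_true(all(an >= 13 & an <= 300 - 12))
    ## half the anchors are long-range
    expect_gte(sum(an[, 2] - an[, 1] >= 150), nrow(an) / 2 - 1)
})

test_that("contact decay follows the configured power law", {
    cfg <- simConfig(nBins = 200L, depth = 2e6, seed = 5,
                     compartmentAmplitude = 0, tadBoost = 1, loopBoost = 1,
                     decayExponent = 1.5)
    sim <- simulateContactMap(cfg, nLoops = 0L)
    m <- counts(mergeReplicates(sim$matrices))
    mu <- sapply(c(2, 4, 8, 16), function(k) {
        i <- seq_len(200 - k)
        mean(m[cbind(i, i + k)])
    })
    ## successive distance doublings reduce the mean by ~2^-1.5
    ratios <- mu[-1] / mu[-length(mu)]
    expect_true(all(abs(log2(ratios) + 1.5) < 0.2))
})

test_that("perturbationSchedule validates its inputs", {
    expect_error(perturbationSchedule(timepoints = c("0", "2"),
                                      attenuation = 1),
                 "length")
    expect_error(perturbationSchedule(
        timepoints = c("0", "2"),
        attenuation = c(1, 1), ampMultiplier = c(1, 1),
        homogenize = c(0, 0), loopAttenuation = c(1, 1),
        switches = data.frame(onset = "99", recoverable = TRUE)),
        "onset")
    s <- perturbationSchedule()
    expect_s3_class(s, "perturbationSchedule")
    expect_identical(s$timepoints[1], "0")
})

test_that("timecourse shares baseline truth and realizes switches", {
    cfg <- simConfig(nBins = 400L, depth = 1e5, seed = 11)
    tc <- simulateTimecourse(cfg, perturbationSchedule(), nLoops = 4L)
    expect_named(tc, c("0", "1", "2", "5", "10", "30", "withdrawal"))
    sr <- switchRegions(tc[["0"]]$truth)
    expect_equal(nrow(sr), 4L)
    expect_setequal(sr$label,
                    c("early-recoverable", "early-irrecoverable",
                      "late-recoverable", "late-irrecoverable"))
    e0 <- trueProfile(tc[["0"]]$truth)
    ## baseline profile carries no switch yet
    base <- truthParams(tc[["0"]]$truth)$baselineProfile
    expect_identical(e0, base)
    ## each switch region flips sign exactly from its onset onward; at
    ## timepoints with homogenization the magnitudes are compressed toward
    ## the segment mean, so only the sign is exact there
    tps <- names(tc)
    sched <- perturbationSchedule()
    for (r in seq_len(nrow(sr))) {
        bb <- sr$start[r]:sr$end[r]
        onsetIdx <- match(sr$onset[r], tps)
        for (k in seq_along(tps)) {
            e <- trueProfile(tc[[tps[k]]]$truth)
            flipped <- if (tps[k] == "withdrawal") !sr$recoverable[r]
                       else k >= onsetIdx
            want <- if (flipped) -base[bb] else base[bb]
            if (sched$homogenize[k] == 0) {
                expect_identical(e[bb], want)
            } else {
                expect_identical(sign(e[bb]), sign(want))
            }
        }
    }
})

test_that("planted TAD events modify boundaries as declared", {
    cfg <- simConfig(nBins = 400L, depth = 1e5, seed = 13)
    ev <- data.frame(timepoint = c("2", "2", "2"),
                     type = c("fusion", "shift", "separation"),
                     n = c(1L, 1L, 1L))
    tc <- simulateTimecourse(cfg, bareSchedule(c("0", "2"), tadEvents = ev),
                             nLoops = 0L)
    b0 <- trueBoundaries(tc[["0"]]$truth)
    b2 <- trueBoundaries(tc[["2"]]$truth)
    planted <- truthParams(tc[["2"]]$truth)$tadEvents
    expect_equal(nrow(planted), 3L)
    lost <- planted$lost[!is.na(planted$lost)]
    gained <- planted$gained[!is.na(planted$gained)]
    expect_true(all(lost %in% b0) && !any(lost %in% b2))
    expect_true(all(gained %in% b2) && !any(gained %in% b0))
    sh <- planted[planted$type == "shift", ]
    expect_equal(sh$gained, sh$lost + 2L)
})

test_that("simulateSignalTrack couples signal to the profile", {
    e <- rep(c(1, -1), each = 100)
    tr <- simulateSignalTrack(e, enrichment = 2, noiseSd = 0.1, seed = 1)
    v <- trackValues(tr)
    expect_true(all(v > 0))
    expect_gt(mean(v[1:100]), mean(v[101:200]))
    ## zero enrichment decouples
    tr0 <- simulateSignalTrack(e, enrichment = 0, noiseSd = 0.1, seed = 1)
    expect_lt(abs(cor(trackValues(tr0), e)), 0.2)
})

test_that("point patterns and trajectories respect their windows", {
    p <- simulatePointPattern("csr", areaSide = 2, nPoints = 50, seed = 1)
    expect_equal(dim(p$points), c(50L, 2L))
    expect_true(all(p$points >= 0 & p$points <= 2))
    expect_equal(p$areaS, 4)
    cl <- simulatePointPattern("clustered", seed = 2)
    expect_true(all(cl$points >= 0 & cl$points <= 1))
    tr <- simulateTrajectories(D = 0.1, dt = 0.05, nSteps = 20,
                               nParticles = 3, seed = 1)
    expect_equal(nrow(tr), 3 * 21)
    expect_equal(attr(tr, "dt"), 0.05)
    expect_true(all(tr$x[tr$frame == 0] == 0))
})

test_that("trajectory increments have variance 2 D dt", {
    D <- 0.2; dt <- 0.1
    tr <- simulateTrajectories(D, dt, nSteps = 400, nParticles = 50,
                               seed = 9)
    dx <- unlist(lapply(split(tr$x, tr$particle), diff))
    expect_lt(abs(var(dx) / (2 * D * dt) - 1), 0.05)
})
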