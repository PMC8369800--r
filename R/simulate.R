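## Synthetic Hi-C generator with planted ground truth.
##
## The contact intensity for bins i, j is
##   lambda_ij  propto  |i-j|^-alpha * exp(c * e_i * e_j)
##                      * tadBoost^[i,j in same TAD]
##                      * loopBoost^[(i,j) within 1 bin of an anchor pair]
## scaled so the expected total equals `depth`, observed through independent
## Poisson draws per replicate. The planted eigenprofile e is piecewise
## constant over compartment segments whose breakpoints are a subset of the
## TAD boundaries (a TAD always lies inside one compartment), so TAD-level
## smoothing of a recovered profile is a proper denoiser.

planted_segments <- function(nBins) {
    ## TAD lengths 8..16 bins (~320-640 kb at 40 kb); compartment segments
    ## merge consecutive TADs to a mean length of ~25 bins.
    lens <- integer()
    while (sum(lens) < nBins) lens <- c(lens, sample(8:16, 1L))
    ends <- cumsum(lens)
    ends <- ends[ends < nBins]
    tadBoundaries <- as.integer(ends)
    nTad <- length(tadBoundaries) + 1L
    newSeg <- c(TRUE, runif(nTad - 1L) < 0.5)
    segId <- cumsum(newSeg)
    tadStart <- c(1L, tadBoundaries + 1L)
    tadEnd <- c(tadBoundaries, nBins)
    segStart <- tapply(tadStart, segId, min)
    segEnd <- tapply(tadEnd, segId, max)
    vals <- runif(length(segStart), -1, 1)
    e <- numeric(nBins)
    for (s in seq_along(segStart)) e[segStart[s]:segEnd[s]] <- vals[s]
    list(e = e, tadBoundaries = tadBoundaries,
         segments = data.frame(start = as.integer(segStart),
                               end = as.integer(segEnd), value = vals))
}

planted_anchors <- function(nBins, nLoops = 20L, margin = 13L) {
    ## Half short-range (25-100 bins apart), half long-range (>= half the
    ## chromosome), all clear of the matrix edges so APA windows fit.
    nShort <- nLoops %/% 2L
    nLong <- nLoops - nShort
    lo <- margin
    hi <- nBins - margin + 1L
    span <- hi - lo
    dShortMax <- min(100L, span %/% 3L)
    dShortMin <- min(25L, max(5L, dShortMax - 1L))
    short <- t(vapply(seq_len(nShort), function(z) {
        d <- sample(dShortMin:dShortMax, 1L)
        i <- sample(lo:(hi - d), 1L)
        c(i, i + d)
    }, integer(2)))
    longMin <- min(as.integer(0.5 * nBins), span - 1L)
    long <- t(vapply(seq_len(nLong), function(z) {
        d <- sample(longMin:(span - 1L), 1L)
        i <- sample(lo:(hi - d), 1L)
        c(i, i + d)
    }, integer(2)))
    a <- rbind(short, long)
    colnames(a) <- c("i", "j")
    a[!duplicated(a), , drop = FALSE]
}

lambda_matrix <- function(e, tadBoundaries, anchors, config,
                          ampMultiplier = 1, attenuation = 1,
                          longRangeMinBins = Inf, loopAttenuation = 1,
                          loopBoost = NULL) {
    n <- length(e)
    idx <- seq_len(n)
    d <- abs(outer(idx, idx, "-"))
    d[d == 0L] <- 1L                     # diagonal treated as distance 1
    lam <- d^(-config@decayExponent)
    amp <- config@compartmentAmplitude * ampMultiplier
    if (amp != 0) lam <- lam * exp(amp * outer(e, e))
    if (config@tadBoost != 1) {
        tadId <- findInterval(idx, c(1L, tadBoundaries + 1L))
        same <- outer(tadId, tadId, "==")
        lam[same] <- lam[same] * config@tadBoost
    }
    if (is.null(loopBoost)) loopBoost <- config@loopBoost
    if (nrow(anchors) && loopBoost != 1) {
        for (r in seq_len(nrow(anchors))) {
            i <- anchors[r, 1]; j <- anchors[r, 2]
            b <- if (abs(j - i) >= longRangeMinBins)
                1 + loopAttenuation * (loopBoost - 1) else loopBoost
            ii <- max(1L, i - 1L):min(n, i + 1L)
            jj <- max(1L, j - 1L):min(n, j + 1L)
            lam[ii, jj] <- lam[ii, jj] * b
            lam[jj, ii] <- lam[jj, ii] * b
        }
    }
    if (attenuation != 1 && is.finite(longRangeMinBins)) {
        far <- d >= longRangeMinBins
        lam[far] <- lam[far] * attenuation
    }
    lam
}

draw_replicates <- function(lam, config, chromName = "chrS") {
    n <- nrow(lam)
    ut <- upper.tri(lam, diag = TRUE)
    lamU <- lam[ut]
    lamU <- lamU * config@depth / sum(lamU)
    lapply(seq_len(config@nReplicates), function(r) {
        cnt <- matrix(0, n, n)
        cnt[ut] <- rpois(length(lamU), lamU)
        cnt <- cnt + t(cnt) - diag(diag(cnt))
        contactMatrix(cnt, chrom = chromName, binSize = config@binSize)
    })
}

#' Simulate a multi-replicate Hi-C contact map with planted truth
#'
#' Draws a planted compartment eigenprofile, TAD boundaries and loop
#' anchors, builds the contact intensity described in the package vignette
#' and returns independent Poisson replicates sharing that intensity.
#'
#' @param config a \linkS4class{SimConfig}
#' @param truth optional \linkS4class{PlantedTruth} to reuse (its profile,
#'   boundaries and anchors) instead of drawing new ones
#' @param nLoops number of planted loop-anchor pairs
#' @param chromName chromosome name stamped on the simulated matrices
#' @return list with elements \code{matrices} (list of
#'   \linkS4class{ContactMatrix}, one per replicate) and \code{truth}
#'   (\linkS4class{PlantedTruth})
#' @examples
#' sim <- simulateContactMap(simConfig(nBins = 100, depth = 1e5, seed = 3))
#' sim$truth
#' @export
simulateContactMap <- function(config, truth = NULL, nLoops = 20L,
                               chromName = "chrS") {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    set.seed(config@seed)
    if (is.null(truth)) {
        seg <- planted_segments(config@nBins)
        anchors <- planted_anchors(config@nBins, nLoops)
        truth <- new("PlantedTruth", trueProfile = seg$e,
                     trueBoundaries = seg$tadBoundaries,
                     loopAnchors = anchors,
                     switchRegions = data.frame(),
                     params = list(config = config))
    }
    lam <- lambda_matrix(truth@trueProfile, truth@trueBoundaries,
                         truth@loopAnchors, config)
    list(matrices = draw_replicates(lam, config, chromName), truth = truth)
}

#' Perturbation schedule for a simulated timecourse
#'
#' Describes, per timepoint, the long-range distance attenuation, the
#' compartment-amplitude multiplier, a homogenization factor that compresses
#' the magnitude of the planted eigenprofile toward its mean (making
#' same-sign interactions more uniform), an attenuation of the loop boost at
#' long-range anchors (condensate-mediated loops dissolving), and planted
#' TAD boundary deletions/insertions/shifts. Compartment switch regions are
#' requested by onset timepoint and recoverability; the generator realizes
#' them on planted compartment segments.
#'
#' The default emulates a transient condensate-disruption timecourse:
#' short exposures (1/2/5 min) lose long-range contacts, sharpen and
#' homogenize compartments and melt long-range loops; long exposures
#' (10/30 min) do the opposite; withdrawal returns to baseline except for
#' irrecoverable switches.
#'
#' @param timepoints timepoint names, baseline first
#' @param attenuation per-timepoint multiplier on intensities at distances
#'   beyond \code{longRangeMinBp}
#' @param ampMultiplier per-timepoint compartment-amplitude multiplier
#' @param homogenize per-timepoint profile-compression factor in [0, 1]
#' @param loopAttenuation per-timepoint multiplier on the excess loop boost
#'   of long-range anchors
#' @param longRangeMinBp distance above which attenuation applies
#' @param switches data.frame(onset, recoverable) of requested switch
#'   regions
#' @param tadEvents data.frame(timepoint, type, n) of requested TAD events,
#'   type in "fusion" (boundary deletion), "separation" (insertion),
#'   "shift" (deletion plus insertion 2 bins away)
#' @return a list with class "perturbationSchedule"
#' @export
perturbationSchedule <- function(
        timepoints = c("0", "1", "2", "5", "10", "30", "withdrawal"),
        attenuation   = c(1, 0.7, 0.5, 0.6, 1.0, 1.2, 1),
        ampMultiplier = c(1, 1.3, 1.5, 1.4, 0.8, 0.7, 1),
        homogenize    = c(0, 0.3, 0.6, 0.5, 0.0, 0.0, 0),
        loopAttenuation = c(1, 0.5, 0.3, 0.4, 1.0, 1.0, 1),
        longRangeMinBp = 5e6,
        switches = data.frame(onset = c("1", "2", "10", "30"),
                              recoverable = c(TRUE, FALSE, TRUE, FALSE)),
        tadEvents = data.frame(
            timepoint = c("2", "2", "30"),
            type = c("fusion", "shift", "separation"),
            n = c(2L, 1L, 2L))) {
    stopifnot(length(timepoints) >= 2,
              length(attenuation) == length(timepoints),
              length(ampMultiplier) == length(timepoints),
              length(homogenize) == length(timepoints),
              length(loopAttenuation) == length(timepoints))
    if (nrow(switches) && !all(switches$onset %in% timepoints[-1]))
        stop("switch onset timepoints must be treated timepoints")
    if (nrow(tadEvents) && !all(tadEvents$timepoint %in% timepoints[-1]))
        stop("tadEvents timepoints must be treated timepoints")
    structure(list(timepoints = timepoints, attenuation = attenuation,
                   ampMultiplier = ampMultiplier, homogenize = homogenize,
                   loopAttenuation = loopAttenuation,
                   longRangeMinBp = longRangeMinBp, switches = switches,
                   tadEvents = tadEvents),
              class = "perturbationSchedule")
}

#' Identity schedule (all perturbations off)
#' @param timepoints timepoint names, baseline first
#' @return a perturbationSchedule whose timepoints are exchangeable
#' @export
identitySchedule <- function(timepoints = c("0", "2", "30", "withdrawal")) {
    k <- length(timepoints)
    perturbationSchedule(timepoints = timepoints,
                         attenuation = rep(1, k), ampMultiplier = rep(1, k),
                         homogenize = rep(0, k),
                         loopAttenuation = rep(1, k),
                         switches = data.frame(onset = character(),
                                               recoverable = logical()),
                         tadEvents = data.frame(timepoint = character(),
                                                type = character(),
                                                n = integer()))
}

early_timepoints <- function() c("1", "2", "5")

apply_switches <- function(e, segments, switches, timepoint, timepoints) {
    ## A requested switch flips the sign of e on one compartment segment from
    ## its onset timepoint on; recoverable switches revert at withdrawal.
    if (!nrow(switches)) return(list(e = e, regions = data.frame()))
    cand <- segments[abs(segments$value) >= 0.1 & abs(segments$value) <= 0.5 &
                     (segments$end - segments$start + 1L) >= 10L, ]
    if (nrow(cand) < nrow(switches))
        cand <- segments[(segments$end - segments$start + 1L) >= 8L, ]
    if (nrow(cand) < nrow(switches))
        stop("not enough planted segments to realize the requested switches")
    pick <- cand[sample(nrow(cand), nrow(switches)), ]
    regions <- data.frame(start = pick$start, end = pick$end,
                          onset = switches$onset,
                          recoverable = switches$recoverable)
    regions$label <- paste0(
        ifelse(regions$onset %in% early_timepoints(), "early", "late"),
        "-", ifelse(regions$recoverable, "recoverable", "irrecoverable"))
    tpIdx <- match(timepoint, timepoints)
    for (r in seq_len(nrow(regions))) {
        onsetIdx <- match(regions$onset[r], timepoints)
        active <- if (timepoint == "withdrawal")
            !regions$recoverable[r] else tpIdx >= onsetIdx
        if (active) {
            b <- regions$start[r]:regions$end[r]
            e[b] <- -e[b]
        }
    }
    list(e = e, regions = regions)
}

apply_tad_events <- function(tadBoundaries, nBins, tadEvents, timepoint,
                             segmentEdges = integer()) {
    ev <- tadEvents[tadEvents$timepoint == timepoint, , drop = FALSE]
    out <- data.frame(timepoint = character(), type = character(),
                      lost = integer(), gained = integer())
    b <- tadBoundaries
    if (!nrow(ev)) return(list(boundaries = b, events = out))
    ## only boundaries away from compartment-segment edges are deletable:
    ## an eigenprofile step survives the loss of the TAD boost and would be
    ## re-detected, so deleting there would not realize the planted event
    nearEdge <- vapply(b, function(x)
        any(abs(x - segmentEdges) <= 2L), logical(1))
    interior <- b[b > 5L & b < nBins - 5L & !nearEdge]
    for (r in seq_len(nrow(ev))) {
        for (k in seq_len(ev$n[r])) {
            if (ev$type[r] == "fusion") {
                del <- sample(interior[interior %in% b], 1L)
                b <- setdiff(b, del)
                out <- rbind(out, data.frame(timepoint = timepoint,
                    type = "fusion", lost = del, gained = NA_integer_))
            } else if (ev$type[r] == "shift") {
                del <- sample(interior[interior %in% b], 1L)
                gain <- del + 2L
                b <- sort(union(setdiff(b, del), gain))
                out <- rbind(out, data.frame(timepoint = timepoint,
                    type = "shift", lost = del, gained = gain))
            } else if (ev$type[r] == "separation") {
                bb <- sort(b)
                starts <- c(1L, bb + 1L); ends <- c(bb, nBins)
                big <- which(ends - starts + 1L >= 12L)
                dpick <- sample(big, 1L)
                gain <- as.integer((starts[dpick] + ends[dpick]) %/% 2L)
                b <- sort(union(b, gain))
                out <- rbind(out, data.frame(timepoint = timepoint,
                    type = "separation", lost = NA_integer_, gained = gain))
            } else stop("unknown TAD event type: ", ev$type[r])
        }
    }
    list(boundaries = sort(as.integer(b)), events = out)
}

#' Simulate a perturbation timecourse of Hi-C maps
#'
#' All timepoints share one planted baseline truth (profile, TAD
#' boundaries, loop anchors) and one bin table; each timepoint's intensity
#' applies that timepoint's perturbations before Poisson sampling.
#'
#' @param config a \linkS4class{SimConfig} (its seed drives everything)
#' @param schedule a \code{\link{perturbationSchedule}}
#' @param nLoops number of planted loop-anchor pairs
#' @param chromName chromosome name stamped on the simulated matrices
#' @return named list over timepoints; each element has \code{matrices}
#'   (replicate \linkS4class{ContactMatrix} list) and \code{truth}
#'   (\linkS4class{PlantedTruth} carrying that timepoint's effective
#'   profile, boundaries and the realized switch-region table)
#' @examples
#' tc <- simulateTimecourse(simConfig(nBins = 120, depth = 2e5, seed = 5),
#'                          identitySchedule())
#' names(tc)
#' @export
simulateTimecourse <- function(config, schedule = perturbationSchedule(),
                               nLoops = 20L, chromName = "chrS") {
    stopifnot(is(config, "SimConfig"),
              inherits(schedule, "perturbationSchedule"))
    set.seed(config@seed)
    seg <- planted_segments(config@nBins)
    anchors <- planted_anchors(config@nBins, nLoops)
    longRangeMinBins <- schedule$longRangeMinBp / config@binSize
    ## realize switch regions and TAD events once, deterministically
    swTemplate <- apply_switches(seg$e, seg$segments, schedule$switches,
                                 schedule$timepoints[1],
                                 schedule$timepoints)
    segEdges <- seg$segments$end[seg$segments$end < config@nBins]
    tadReal <- list()
    for (tp in schedule$timepoints)
        tadReal[[tp]] <- apply_tad_events(seg$tadBoundaries, config@nBins,
                                          schedule$tadEvents, tp,
                                          segmentEdges = segEdges)
    out <- setNames(vector("list", length(schedule$timepoints)),
                    schedule$timepoints)
    for (k in seq_along(schedule$timepoints)) {
        tp <- schedule$timepoints[k]
        e <- seg$e
        regions <- swTemplate$regions
        if (nrow(regions)) {
            tpIdx <- k
            for (r in seq_len(nrow(regions))) {
                onsetIdx <- match(regions$onset[r], schedule$timepoints)
                active <- if (tp == "withdrawal") !regions$recoverable[r]
                          else tpIdx >= onsetIdx
                if (active) {
                    bb <- regions$start[r]:regions$end[r]
                    e[bb] <- -e[bb]
                }
            }
        }
        h <- schedule$homogenize[k]
        if (h > 0) {
            m <- mean(abs(seg$e))
            e <- sign(e) * ((1 - h) * abs(e) + h * m)
        }
        lam <- lambda_matrix(e, tadReal[[tp]]$boundaries, anchors, config,
                             ampMultiplier = schedule$ampMultiplier[k],
                             attenuation = schedule$attenuation[k],
                             longRangeMinBins = longRangeMinBins,
                             loopAttenuation = schedule$loopAttenuation[k])
        truth <- new("PlantedTruth", trueProfile = e,
                     trueBoundaries = tadReal[[tp]]$boundaries,
                     loopAnchors = anchors, switchRegions = regions,
                     params = list(
                         timepoint = tp,
                         attenuation = schedule$attenuation[k],
                         ampMultiplier = schedule$ampMultiplier[k],
                         homogenize = h,
                         loopAttenuation = schedule$loopAttenuation[k],
                         longRangeMinBins = longRangeMinBins,
                         tadEvents = tadReal[[tp]]$events,
                         baselineProfile = seg$e,
                         segments = seg$segments))
        out[[tp]] <- list(matrices = draw_replicates(lam, config,
                                                     chromName),
                          truth = truth)
    }
    out
}

#' Simulate a compartment-correlated binned signal track
#'
#' \code{signal_i = exp(enrichment * profile_i + eps_i)} with Gaussian
#' noise, emulating e.g. a condensate-component ChIP signal concentrated on
#' high-eigenprofile bins.
#'
#' @param profile per-bin real profile (e.g. a planted eigenprofile)
#' @param enrichment log-linear coupling of signal to profile
#' @param noiseSd standard deviation of the log-normal noise
#' @param seed RNG seed
#' @param chrom,binSize metadata for the returned track
#' @return a \linkS4class{SignalTrack}
#' @export
simulateSignalTrack <- function(profile, enrichment = 2, noiseSd = 0.1,
                                seed = 1L, chrom = "chrS", binSize = 40000) {
    set.seed(seed)
    eps <- if (noiseSd > 0) rnorm(length(profile), 0, noiseSd) else 0
    signalTrack(exp(enrichment * profile + eps), chrom = chrom,
                binSize = binSize)
}

#' Simulate a 2D point pattern
#'
#' Complete spatial randomness ("csr") or a Thomas-type parent-offspring
#' cluster process ("clustered"); offspring positions are wrapped back into
#' the observation square so the planted intensity is uniform.
#'
#' @param kind "csr" or "clustered"
#' @param areaSide side length of the square observation window
#' @param nPoints number of points (csr)
#' @param parentRate parent intensity per unit area (clustered)
#' @param meanOffspring mean offspring per parent (clustered)
#' @param offspringScale Gaussian scatter of offspring around parents
#' @param seed RNG seed
#' @return list with \code{points} (n x 2 matrix) and \code{areaS}
#' @export
simulatePointPattern <- function(kind = c("csr", "clustered"), areaSide = 1,
                                 nPoints = 100L, parentRate = 20,
                                 meanOffspring = 5, offspringScale = 0.02,
                                 seed = 1L) {
    kind <- match.arg(kind)
    stopifnot(areaSide > 0)
    set.seed(seed)
    if (kind == "csr") {
        pts <- cbind(x = runif(nPoints, 0, areaSide),
                     y = runif(nPoints, 0, areaSide))
    } else {
        nParents <- rpois(1, parentRate * areaSide^2)
        if (nParents == 0) nParents <- 1L
        px <- runif(nParents, 0, areaSide)
        py <- runif(nParents, 0, areaSide)
        nOff <- rpois(nParents, meanOffspring)
        xs <- rep(px, nOff); ys <- rep(py, nOff)
        if (offspringScale > 0) {
            xs <- xs + rnorm(length(xs), 0, offspringScale)
            ys <- ys + rnorm(length(ys), 0, offspringScale)
        }
        pts <- cbind(x = xs %% areaSide, y = ys %% areaSide)
    }
    list(points = pts, areaS = areaSide^2)
}

#' Simulate 2D Brownian trajectories with localization noise
#'
#' Per-axis increments are Normal(0, 2 D dt); independent Gaussian
#' localization error is added to every observed position.
#'
#' @param D diffusion coefficient (area / time)
#' @param dt frame interval (time)
#' @param nSteps number of steps per trajectory (nSteps + 1 frames)
#' @param nParticles number of trajectories
#' @param locErrorSd localization error standard deviation (length)
#' @param seed RNG seed
#' @return data.frame(particle, frame, x, y) with attribute \code{dt}
#' @export
simulateTrajectories <- function(D, dt, nSteps = 100L, nParticles = 10L,
                                 locErrorSd = 0, seed = 1L) {
    stopifnot(D >= 0, dt > 0, nSteps >= 1, nParticles >= 1)
    set.seed(seed)
    sdStep <- sqrt(2 * D * dt)
    nFrames <- nSteps + 1L
    traj <- lapply(seq_len(nParticles), function(p) {
        x <- cumsum(c(0, rnorm(nSteps, 0, sdStep)))
        y <- cumsum(c(0, rnorm(nSteps, 0, sdStep)))
        if (locErrorSd > 0) {
            x <- x + rnorm(nFrames, 0, locErrorSd)
            y <- y + rnorm(nFrames, 0, locErrorSd)
        }
        data.frame(particle = p, frame = seq_len(nFrames) - 1L, x = x, y = y)
    })
    out <- do.call(rbind, traj)
    attr(out, "dt") <- dt
    out
}
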