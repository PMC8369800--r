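## A/B compartment analysis: leading eigenvector (PC1) of the O/E Pearson
## correlation matrix, A/B assignment oriented by a gene-density-like
## track, TAD-level smoothing, per-bin compartment strength, saddle
## aggregation, PC1-range interaction grids, interaction homogeneity,
## compartment regions and the multi-timepoint switch classifier.

#' Compute the compartment eigenvector (PC1)
#'
#' O/E matrix -> Pearson correlation across bins (masked bins removed) ->
#' leading eigenvector, sign-oriented so its correlation with a
#' gene-density-like track is positive (gene-rich = A = positive), and
#' rescaled so the 99th percentile of |pc1| is 1.
#'
#' @param cm an O/E \linkS4class{ContactMatrix}
#'   (see \code{\link{oeTransform}})
#' @param orientationTrack a \linkS4class{SignalTrack} correlating with
#'   activity (e.g. gene density); bins with higher signal orient to A
#' @param timepoint name recorded in the profile
#' @param lowConfidenceFraction flag the profile when PC1 explains less
#'   than this fraction of the total correlation
#' @return a \linkS4class{CompartmentProfile}
#' @export
computePC1 <- function(cm, orientationTrack, timepoint = "0",
                       lowConfidenceFraction = 0.1) {
    stopifnot(matrixKind(cm) == "oe")
    m <- counts(cm)
    n <- nrow(m)
    keep <- which(!mask(cm))
    sub <- m[keep, keep, drop = FALSE]
    sdv <- apply(sub, 2, sd, na.rm = TRUE)
    if (any(!is.finite(sdv)) || any(sdv == 0))
        stop("degenerate correlation matrix: constant O/E rows")
    ## distances whose stratum mean is undefined leave NA cells; use
    ## pairwise-complete correlations (complete case takes the fast path)
    cc <- if (anyNA(sub)) cor(sub, use = "pairwise.complete.obs") else
        cor(sub)
    if (anyNA(cc)) cc[is.na(cc)] <- 0
    eg <- eigen(cc, symmetric = TRUE)
    v <- eg$vectors[, 1]
    frac <- eg$values[1] / sum(abs(eg$values))
    ori <- trackValues(orientationTrack)[keep]
    if (cor(v, ori) < 0) v <- -v
    sc <- quantile(abs(v), 0.99)
    if (sc > 0) v <- v / sc
    pc <- rep(NA_real_, n)
    pc[keep] <- v
    lab <- rep("filtered", n)
    lab[keep] <- ifelse(v > 0, "A", "B")
    new("CompartmentProfile", chrom = chrom(cm), binSize = binSize(cm),
        pc1 = pc, label = lab, strength = rep(NA_real_, n),
        timepoint = timepoint, eigenvalueFraction = frac,
        lowConfidence = frac < lowConfidenceFraction)
}

#' Smooth a compartment profile at TAD level
#'
#' Replaces each bin's PC1 by the mean PC1 of its TAD (a TAD always lies in
#' one compartment) and re-derives A/B labels. Bins outside any domain are
#' assigned to the nearest domain with a warning.
#'
#' @param profile a \linkS4class{CompartmentProfile}
#' @param tads a \linkS4class{TADSet} tiling the chromosome
#' @return smoothed \linkS4class{CompartmentProfile}
#' @export
smoothByTADs <- function(profile, tads) {
    pc <- pc1(profile)
    n <- length(pc)
    d <- domains(tads)
    tadId <- rep(NA_integer_, n)
    for (t in seq_len(nrow(d))) tadId[d[t, 1]:d[t, 2]] <- t
    if (anyNA(tadId)) {
        warning("bins outside any TAD assigned to the nearest domain")
        out <- which(is.na(tadId))
        inb <- which(!is.na(tadId))
        tadId[out] <- tadId[inb[pmax(1,
            findInterval(out, inb, all.inside = TRUE))]]
    }
    sm <- ave(pc, tadId, FUN = function(z) mean(z, na.rm = TRUE))
    sm[is.nan(sm)] <- NA_real_
    keep <- profile@label != "filtered" & !is.na(sm)
    lab <- rep("filtered", n)
    lab[keep] <- ifelse(sm[keep] > 0, "A", "B")
    sm[!keep] <- NA_real_
    new("CompartmentProfile", chrom = chrom(profile),
        binSize = binSize(profile), pc1 = sm, label = lab,
        strength = profile@strength, timepoint = profile@timepoint,
        eigenvalueFraction = profile@eigenvalueFraction,
        lowConfidence = profile@lowConfidence)
}

#' Per-bin compartment strength
#'
#' For a bin of type T, mean same-type O/E divided by mean opposite-type
#' O/E (excluding the bin itself and masked bins). Bins with no
#' opposite-type partner get NA.
#'
#' @param oeCm an O/E \linkS4class{ContactMatrix}
#' @param profile a labeled \linkS4class{CompartmentProfile}
#' @return numeric vector of per-bin strengths
#' @export
perBinStrength <- function(oeCm, profile) {
    m <- counts(oeCm)
    n <- nrow(m)
    lab <- compartmentLabels(profile)
    strength <- rep(NA_real_, n)
    isA <- lab == "A"; isB <- lab == "B"
    for (i in seq_len(n)) {
        if (lab[i] == "filtered") next
        same <- if (isA[i]) isA else isB
        opp <- if (isA[i]) isB else isA
        same[i] <- FALSE
        sv <- mean(m[i, same], na.rm = TRUE)
        ov <- mean(m[i, opp], na.rm = TRUE)
        if (is.finite(sv) && is.finite(ov) && ov > 0)
            strength[i] <- sv / ov
    }
    strength
}

#' Classify per-bin compartment-strength changes
#'
#' Compares treated/baseline strength ratios against \code{fold} and
#' \code{1/fold}.
#'
#' @param strengthT,strength0 per-bin strengths at the treated timepoint
#'   and baseline
#' @param fold fold-change threshold (default 2)
#' @return list(class per bin, proportions over classified bins)
#' @export
classifyStrengthChange <- function(strengthT, strength0, fold = 2) {
    r <- strengthT / strength0
    cls <- rep(NA_character_, length(r))
    ok <- is.finite(r)
    cls[ok & r >= fold] <- "strengthened"
    cls[ok & r <= 1 / fold] <- "weakened"
    cls[ok & r > 1 / fold & r < fold] <- "unchanged"
    prop <- prop.table(table(factor(cls,
        c("strengthened", "weakened", "unchanged"))))
    list(class = cls, proportions = prop)
}

#' Saddle aggregation of an O/E matrix by PC1 quantiles
#'
#' Bins are trimmed to the \code{qrange} quantiles of PC1, ranked into
#' \code{n} quantile groups, and the grid holds the mean O/E over bin pairs
#' per group pair. The corner strength score is the mean over the extreme
#' 20 percent same-type corners (AA and BB) divided by the mean over the
#' cross-type corners.
#'
#' @param oeCm an O/E \linkS4class{ContactMatrix}
#' @param profile a \linkS4class{CompartmentProfile} (or numeric PC1)
#' @param n number of quantile groups
#' @param qrange PC1 quantile trimming range
#' @return list(grid, score, n, qrange)
#' @export
saddle <- function(oeCm, profile, n = 50, qrange = c(0.005, 0.995)) {
    pc <- if (is(profile, "CompartmentProfile")) pc1(profile) else profile
    m <- counts(oeCm)
    keep <- which(!mask(oeCm) & !is.na(pc))
    if (length(keep) < n) stop("fewer non-masked bins than quantile groups")
    qq <- quantile(pc[keep], qrange)
    keep <- keep[pc[keep] >= qq[1] & pc[keep] <= qq[2]]
    r <- rank(pc[keep], ties.method = "first")
    grp <- ceiling(r / length(r) * n)
    sub <- m[keep, keep, drop = FALSE]
    grid <- matrix(NA_real_, n, n)
    gs <- split(seq_along(keep), grp)
    for (a in seq_len(n)) for (b in a:n) {
        ia <- gs[[as.character(a)]]; ib <- gs[[as.character(b)]]
        if (is.null(ia) || is.null(ib)) next
        v <- sub[ia, ib, drop = FALSE]
        if (a == b) v <- v[upper.tri(v)]
        grid[a, b] <- grid[b, a] <- mean(v, na.rm = TRUE)
    }
    k <- max(1L, round(0.2 * n))
    lo <- seq_len(k); hi <- (n - k + 1):n
    sameCorner <- c(grid[lo, lo], grid[hi, hi])
    crossCorner <- c(grid[lo, hi], grid[hi, lo])
    score <- mean(sameCorner, na.rm = TRUE) / mean(crossCorner, na.rm = TRUE)
    list(grid = grid, score = score, n = n, qrange = qrange)
}

#' Mean O/E between PC1-range groups
#'
#' Grid cell (p, q) is the mean O/E over bin pairs whose PC1 values fall in
#' ranges p and q respectively (i != j); empty ranges give NA.
#'
#' @param oeCm an O/E \linkS4class{ContactMatrix}
#' @param profile a \linkS4class{CompartmentProfile} (or numeric PC1)
#' @param ranges named list of c(lo, hi) PC1 intervals (lo exclusive, hi
#'   inclusive); must be disjoint
#' @return matrix of group-mean O/E
#' @export
interactionsByPC1Range <- function(oeCm, profile, ranges) {
    pc <- if (is(profile, "CompartmentProfile")) pc1(profile) else profile
    lim <- do.call(rbind, ranges)
    o <- order(lim[, 1])
    if (any(lim[o, 1][-1] < lim[o, 2][-nrow(lim)]))
        stop("PC1 ranges must be disjoint")
    m <- counts(oeCm)
    members <- lapply(ranges, function(rg)
        which(!mask(oeCm) & !is.na(pc) & pc > rg[1] & pc <= rg[2]))
    k <- length(ranges)
    grid <- matrix(NA_real_, k, k,
                   dimnames = list(names(ranges), names(ranges)))
    for (p in seq_len(k)) for (q in p:k) {
        ip <- members[[p]]; iq <- members[[q]]
        if (!length(ip) || !length(iq)) next
        v <- m[ip, iq, drop = FALSE]
        if (p == q) { if (length(ip) < 2) next; v <- v[upper.tri(v)] }
        grid[p, q] <- grid[q, p] <- mean(v, na.rm = TRUE)
    }
    grid
}

#' Interaction homogeneity (reciprocal squared coefficient of variation)
#'
#' \code{mean(v)^2 / var(v)} with the sample variance; an all-equal vector
#' returns +Inf.
#'
#' @param groupMeans vector of group-mean O/E values (at least 2, positive
#'   mean)
#' @return homogeneity value
#' @examples
#' homogeneity(c(1, 2, 3))  # 4
#' @export
homogeneity <- function(groupMeans) {
    groupMeans <- groupMeans[is.finite(groupMeans)]
    stopifnot(length(groupMeans) >= 2, mean(groupMeans) > 0)
    v <- var(groupMeans)
    if (v == 0) return(Inf)
    mean(groupMeans)^2 / v
}

#' Decile-group means of same-type interactions
#'
#' Splits the bins of one compartment type into \code{nGroups} equal-count
#' PC1 groups and returns the mean O/E between group pairs (the inputs of
#' the homogeneity statistic).
#'
#' @param oeCm an O/E \linkS4class{ContactMatrix}
#' @param profile a labeled \linkS4class{CompartmentProfile}
#' @param type "A" or "B"
#' @param nGroups number of equal-count PC1 groups
#' @return vector of group-pair mean O/E values
#' @export
sameTypeGroupMeans <- function(oeCm, profile, type = "A", nGroups = 10) {
    pc <- pc1(profile)
    sel <- which(compartmentLabels(profile) == type & !mask(oeCm))
    if (length(sel) < 2 * nGroups)
        stop("too few ", type, " bins for ", nGroups, " groups")
    r <- rank(pc[sel], ties.method = "first")
    grp <- ceiling(r / length(r) * nGroups)
    m <- counts(oeCm)
    gs <- split(sel, grp)
    out <- c()
    for (a in seq_len(nGroups)) for (b in a:nGroups) {
        v <- m[gs[[a]], gs[[b]], drop = FALSE]
        if (a == b) v <- v[upper.tri(v)]
        out <- c(out, mean(v, na.rm = TRUE))
    }
    out
}

#' Compartment regions as maximal same-label runs
#'
#' @param profile a labeled \linkS4class{CompartmentProfile}
#' @return \code{GRanges} with metadata column \code{label}
#' @export
compartmentRegions <- function(profile) {
    lab <- compartmentLabels(profile)
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    bs <- binSize(profile)
    gr <- GRanges(chrom(profile),
                  IRanges(start = (starts - 1L) * bs + 1L, end = ends * bs))
    gr$label <- r$values
    gr
}

#' Size statistics of compartment regions
#' @param regions \code{GRanges} from \code{\link{compartmentRegions}}
#' @param label optional label filter ("A" or "B")
#' @return list(meanSize, totalLength) in bp
#' @export
regionSizeStats <- function(regions, label = NULL) {
    if (!is.null(label)) regions <- regions[regions$label == label]
    list(meanSize = if (length(regions)) mean(width(regions)) else NA_real_,
         totalLength = sum(width(regions)))
}

#' Classify compartment switching over a timecourse
#'
#' Regions are maximal runs of bins with an identical label trajectory
#' across all timepoints. A region is constant when its label at every
#' treated timepoint equals the baseline label, filtered when any timepoint
#' filters it, and a switch otherwise. Switches are early-affected when the
#' first label change occurs at 1/2/5 min and late-affected when at
#' 10/30 min; recoverable when the withdrawal label equals the baseline
#' label. Also reports the hypergeometric enrichment of switch bins among
#' low-PC1 bins (baseline PC1 within \code{lowPC1}).
#'
#' @param profiles named list of \linkS4class{CompartmentProfile} in
#'   timepoint order; names must end with "withdrawal" and start with the
#'   baseline
#' @param lowPC1 interval of baseline PC1 defining "low PC1" bins
#' @return list(regions data.frame, proportions, lowPC1Enrichment)
#' @export
classifySwitch <- function(profiles, lowPC1 = c(-0.5, 0.5)) {
    tps <- names(profiles)
    if (is.null(tps) || length(tps) < 3)
        stop("need named profiles for baseline, treated and withdrawal")
    if (tail(tps, 1) != "withdrawal")
        stop("missing withdrawal timepoint (must be last)")
    labs <- vapply(profiles, compartmentLabels,
                   character(nbins(profiles[[1]])))
    n <- nrow(labs)
    key <- apply(labs, 1, paste, collapse = "|")
    newRun <- c(TRUE, key[-1] != key[-n])
    runId <- cumsum(newRun)
    starts <- which(newRun)
    ends <- c(starts[-1] - 1L, n)
    treatedIdx <- 2:(length(tps) - 1)
    cls <- character(length(starts))
    subtype <- rep(NA_character_, length(starts))
    for (r in seq_along(starts)) {
        lr <- labs[starts[r], ]
        if (any(lr == "filtered")) { cls[r] <- "filtered"; next }
        if (all(lr[treatedIdx] == lr[1])) {
            cls[r] <- paste("constant", lr[1])
        } else {
            cls[r] <- "switch"
            firstChange <- tps[treatedIdx[which(lr[treatedIdx] != lr[1])[1]]]
            onset <- if (firstChange %in% early_timepoints())
                "early-affected" else "late-affected"
            rec <- if (lr[length(lr)] == lr[1]) "recoverable" else
                "irrecoverable"
            subtype[r] <- paste(onset, rec, sep = ", ")
        }
    }
    bs <- binSize(profiles[[1]])
    regions <- data.frame(start = starts, end = ends,
                          startBp = (starts - 1L) * bs, endBp = ends * bs,
                          class = cls, subtype = subtype,
                          t0 = labs[starts, 1],
                          withdrawal = labs[starts, length(tps)])
    nb <- ends - starts + 1L
    prop <- vapply(split(nb, cls), sum, numeric(1)) / sum(nb)
    ## low-PC1 enrichment of switch bins (hypergeometric upper tail)
    pc0 <- pc1(profiles[[1]])
    low <- which(!is.na(pc0) & pc0 > lowPC1[1] & pc0 < lowPC1[2])
    switchBins <- unlist(lapply(which(cls == "switch"),
                                function(r) starts[r]:ends[r]))
    nonFiltered <- which(labs[, 1] != "filtered")
    q <- length(intersect(switchBins, low))
    mm <- length(intersect(low, nonFiltered))
    kk <- length(intersect(switchBins, nonFiltered))
    N <- length(nonFiltered)
    pEnrich <- if (kk > 0 && mm > 0)
        phyper(q - 1, mm, N - mm, kk, lower.tail = FALSE) else NA_real_
    list(regions = regions, proportions = prop,
         lowPC1Enrichment = list(overlap = q, nLow = mm, nSwitch = kk,
                                 nBins = N, p = pEnrich))
}
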