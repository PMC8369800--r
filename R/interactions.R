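## Significant-interaction calling on TAD-pair aggregated contacts,
## condensate-enriched / absent / random classification against a signal
## track, distance distributions, and aggregate peak analysis (APA).

#' Aggregate contact counts over TAD pairs
#'
#' \code{observed(p, q)} sums raw counts over bin pairs with one end in
#' domain p and the other in q (intra-domain cells count each unordered bin
#' pair once). Marginals count, per domain, the contacts with at least one
#' end inside it; the grand total counts every unordered contact once.
#' An expected table aggregates the chromosome's distance-decay mean over
#' the same bin pairs.
#'
#' @param cm a raw \linkS4class{ContactMatrix}
#' @param tads a \linkS4class{TADSet} tiling the chromosome
#' @return list(observed, expected, marginals, total, domains, binSize)
#' @export
aggregateTADPairs <- function(cm, tads) {
    m <- counts(cm)
    n <- nrow(m)
    d <- domains(tads)
    nT <- nrow(d)
    memb <- matrix(0, n, nT)
    for (t in seq_len(nT)) memb[d[t, 1]:d[t, 2], t] <- 1
    obs <- t(memb) %*% m %*% memb
    diag(obs) <- vapply(seq_len(nT), function(t) {
        sub <- m[d[t, 1]:d[t, 2], d[t, 1]:d[t, 2], drop = FALSE]
        sum(sub[upper.tri(sub, diag = TRUE)])
    }, numeric(1))
    ## distance-decay background from a robust log-log lowess fit of the
    ## per-distance means: localized enrichments (the very interactions
    ## being tested) would otherwise inflate their own expected values
    dec <- expectedByDistance(m, rep(FALSE, n))
    kk <- seq_len(n - 1L)
    dm <- dec[kk + 1L]
    ok <- is.finite(dm) & dm > 0
    lo <- stats::lowess(log(kk[ok]), log(dm[ok]), f = 0.3, iter = 3L)
    fit <- exp(stats::approx(lo$x, lo$y, xout = log(kk), rule = 2)$y)
    dec <- c(if (is.finite(dec[1]) && dec[1] > 0) dec[1] else fit[1], fit)
    dist <- abs(outer(seq_len(n), seq_len(n), "-"))
    em <- matrix(dec[dist + 1], n, n)
    expd <- t(memb) %*% em %*% memb
    diag(expd) <- vapply(seq_len(nT), function(t) {
        sub <- em[d[t, 1]:d[t, 2], d[t, 1]:d[t, 2], drop = FALSE]
        sum(sub[upper.tri(sub, diag = TRUE)])
    }, numeric(1))
    marg <- rowSums(obs) - diag(obs)   # inter + intra counted once
    marg <- marg + diag(obs)
    total <- sum(obs[upper.tri(obs, diag = TRUE)])
    list(observed = obs, expected = expd, marginals = marg, total = total,
         domains = d, binSize = binSize(cm))
}

#' Call significant TAD-pair interactions
#'
#' Upper-tail hypergeometric p-value of each off-diagonal TAD pair's
#' observed count given the two domain marginals and the grand total,
#' BH-adjusted over all tested pairs; calls require FDR below
#' \code{fdrThresh} and an O/E (against the distance-decay expected) of at
#' least \code{minOE}.
#'
#' @param agg output of \code{\link{aggregateTADPairs}}
#' @param fdrThresh FDR threshold
#' @param minOE minimum observed/expected fold
#' @return data.frame of all tested pairs (domain indices and bp anchors,
#'   observed, expected, oe, p, fdr, significant, distance); calls are rows
#'   with \code{significant == TRUE}
#' @export
callSignificant <- function(agg, fdrThresh = 0.01, minOE = 10) {
    if (agg$total <= 0) stop("zero grand total")
    nT <- nrow(agg$observed)
    pr <- which(upper.tri(agg$observed), arr.ind = TRUE)
    obs <- agg$observed[pr]
    expd <- agg$expected[pr]
    mA <- agg$marginals[pr[, 1]]
    mB <- agg$marginals[pr[, 2]]
    N <- agg$total
    pv <- phyper(obs - 1, mA, pmax(N - mA, 0), pmin(mB, N),
                 lower.tail = FALSE)
    q <- p.adjust(pv, "BH")
    oe <- obs / expd
    d <- agg$domains
    bs <- agg$binSize
    midA <- (d[pr[, 1], 1] + d[pr[, 1], 2]) / 2 * bs
    midB <- (d[pr[, 2], 1] + d[pr[, 2], 2]) / 2 * bs
    data.frame(tadA = pr[, 1], tadB = pr[, 2],
               startA = (d[pr[, 1], 1] - 1L) * bs, endA = d[pr[, 1], 2] * bs,
               startB = (d[pr[, 2], 1] - 1L) * bs, endB = d[pr[, 2], 2] * bs,
               observed = obs, expected = expd, oe = oe, p = pv, fdr = q,
               significant = is.finite(oe) & q < fdrThresh & oe >= minOE,
               distance = abs(midB - midA), class = "none",
               stringsAsFactors = FALSE)
}

anchor_bins <- function(startBp, endBp, binSize, nBins) {
    lo <- floor(startBp / binSize) + 1L
    hi <- ceiling(endBp / binSize)
    pmax(1L, lo):pmin(nBins, hi)
}

#' Classify interactions by signal-track overlap
#'
#' An interaction is condensate-enriched when both anchors overlap at
#' least one top-decile signal bin, condensate-absent when both overlap a
#' bottom-decile bin, and random when both overlap a seed-deterministic
#' uniform 10 percent bin sample (precedence enriched > absent > random;
#' quantile ties broken by bin index).
#'
#' @param calls data.frame from \code{\link{callSignificant}} (bp anchor
#'   columns startA/endA/startB/endB)
#' @param track a \linkS4class{SignalTrack} binned at anchor resolution
#' @param topQ decile fraction
#' @param seed RNG seed for the random bin sample
#' @return \code{calls} with the \code{class} column set
#' @export
classifyBySignal <- function(calls, track, topQ = 0.10, seed = 1L) {
    v <- trackValues(track)
    if (length(unique(v)) == 1L)
        stop("non-informative track: all bin values equal")
    n <- length(v)
    nSel <- max(1L, ceiling(topQ * n))
    topBins <- order(v, decreasing = TRUE)[seq_len(nSel)]
    botBins <- order(v)[seq_len(nSel)]
    set.seed(seed)
    rndBins <- sample(n, nSel)
    bs <- binSize(track)
    cls <- vapply(seq_len(nrow(calls)), function(r) {
        ba <- anchor_bins(calls$startA[r], calls$endA[r], bs, n)
        bb <- anchor_bins(calls$startB[r], calls$endB[r], bs, n)
        if (any(ba %in% topBins) && any(bb %in% topBins)) return("enriched")
        if (any(ba %in% botBins) && any(bb %in% botBins)) return("absent")
        if (any(ba %in% rndBins) && any(bb %in% rndBins)) return("random")
        "none"
    }, character(1))
    calls$class <- cls
    calls
}

#' Distance distributions of interaction classes
#'
#' @param calls classified calls (columns \code{distance}, \code{class})
#' @param classes classes to compare
#' @return list(distances per class, pairwise two-sided rank-sum p matrix)
#' @export
distanceDistribution <- function(calls,
                                 classes = c("enriched", "absent",
                                             "random")) {
    dl <- lapply(classes, function(cl) calls$distance[calls$class == cl])
    names(dl) <- classes
    k <- length(classes)
    pm <- matrix(NA_real_, k, k, dimnames = list(classes, classes))
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
        if (length(dl[[a]]) && length(dl[[b]])) {
            pm[a, b] <- pm[b, a] <- if (identical(sort(dl[[a]]),
                                                  sort(dl[[b]])) &&
                                        length(dl[[a]]) == length(dl[[b]]))
                1 else suppressWarnings(
                    wilcox.test(dl[[a]], dl[[b]])$p.value)
        }
    }
    list(distances = dl, p = pm)
}

#' Aggregate peak analysis
#'
#' Averages (2k+1) x (2k+1) O/E windows centered on each anchor pair;
#' the center score is the mean of the central 3 x 3 cells. Pairs whose
#' windows leave the matrix or touch the diagonal are dropped and counted.
#'
#' @param oeCm an O/E \linkS4class{ContactMatrix}
#' @param anchorPairs two-column matrix of bin pairs (i < j)
#' @param k window half-width in bins
#' @return list(grid, centerScore, cornerMean, n, nFiltered, resolution)
#' @export
apa <- function(oeCm, anchorPairs, k = 5L) {
    m <- counts(oeCm)
    n <- nrow(m)
    ap <- anchorPairs
    if (is.null(dim(ap))) ap <- matrix(ap, ncol = 2)
    i <- pmin(ap[, 1], ap[, 2]); j <- pmax(ap[, 1], ap[, 2])
    ok <- i - k >= 1 & j + k <= n & (j - i) > 2 * k & i + k <= n & j - k >= 1
    nFiltered <- sum(!ok)
    if (!any(ok)) stop("no eligible anchor pair after edge filtering (",
                       nFiltered, " filtered)")
    w <- 2L * k + 1L
    acc <- matrix(0, w, w); cnt <- matrix(0, w, w)
    for (r in which(ok)) {
        sub <- m[(i[r] - k):(i[r] + k), (j[r] - k):(j[r] + k)]
        fin <- is.finite(sub)
        sub[!fin] <- 0
        acc <- acc + sub
        cnt <- cnt + fin
    }
    grid <- acc / cnt
    c0 <- k + 1L
    ctr <- grid[(c0 - 1):(c0 + 1), (c0 - 1):(c0 + 1)]
    ## background corner: the corner farthest from the diagonal
    corner <- grid[1:3, (w - 2):w]
    list(grid = grid, centerScore = mean(ctr, na.rm = TRUE),
         cornerMean = mean(corner, na.rm = TRUE), n = sum(ok),
         nFiltered = nFiltered, resolution = binSize(oeCm))
}
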