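## TopDom-style TAD calling from diamond bin signal, replicate-aware
## differential boundary testing on directionality ratios, reorganization
## classification (fusion / shifting / separation) and aggregate TAD
## analysis.

#' Diamond bin signal
#'
#' \code{signal_i} is the mean contact value in the diamond
#' \{(u, d): i-w < u <= i < d <= i+w\}, i.e. the contacts crossing the
#' prospective boundary between bins i and i+1, truncated at chromosome
#' ends. Local minima mark TAD boundaries.
#'
#' @param cm a balanced \linkS4class{ContactMatrix}
#' @param window diamond half-width in bins
#' @return numeric vector of length nbins - 1 (positions between bins)
#' @export
binSignal <- function(cm, window = 5L) {
    m <- counts(cm)
    n <- nrow(m)
    if (window >= n) stop("window must be smaller than the bin count")
    s <- rep(NA_real_, n - 1L)
    for (i in seq_len(n - 1L)) {
        u <- max(1L, i - window + 1L):i
        d <- (i + 1L):min(n, i + window)
        s[i] <- mean(m[u, d, drop = FALSE], na.rm = TRUE)
    }
    s
}

diamond_values <- function(m, i, window) {
    n <- nrow(m)
    u <- max(1L, i - window + 1L):i
    d <- (i + 1L):min(n, i + window)
    as.numeric(m[u, d, drop = FALSE])
}

#' Call TADs from a balanced contact matrix
#'
#' Candidate boundaries are local minima of the running-mean-smoothed
#' diamond signal within a +/- window neighborhood; each candidate is kept
#' when a one-sided rank-sum test finds its diamond values lower than the
#' diamond values at the interiors of the flanking candidate domains
#' (p < \code{pThresh}). Retained boundaries define domains tiling the
#' chromosome.
#'
#' @param cm a balanced \linkS4class{ContactMatrix}
#' @param window diamond half-width in bins
#' @param pThresh boundary filter p-value threshold
#' @return a \linkS4class{TADSet}
#' @export
callTADs <- function(cm, window = 5L, pThresh = 0.05) {
    m <- counts(cm)
    n <- nrow(m)
    s <- binSignal(cm, window)
    ## light running-mean smoothing before turning-point detection
    sm <- s
    inner <- 2:(length(s) - 1)
    sm[inner] <- (s[inner - 1] + s[inner] + s[inner + 1]) / 3
    cand <- integer()
    for (i in seq_along(sm)) {
        lo <- max(1L, i - window); hi <- min(length(sm), i + window)
        wnd <- sm[lo:hi]
        if (all(is.na(wnd)) || is.na(sm[i])) next
        if (sm[i] <= min(wnd, na.rm = TRUE) &&
            sm[i] < max(wnd, na.rm = TRUE)) cand <- c(cand, i)
    }
    ## collapse candidate plateaus to their center
    if (length(cand) > 1) {
        grp <- cumsum(c(TRUE, diff(cand) > 1))
        cand <- vapply(split(cand, grp),
                       function(z) z[ceiling(length(z) / 2)], integer(1))
    }
    cand <- cand[cand >= 2L & cand <= n - 2L]
    if (!length(cand))
        return(tadSet(integer(), n, chrom(cm), binSize(cm),
                      binSignal = s))
    ## statistical filter: boundary diamond vs flanking domain interiors
    edges <- c(0L, cand, as.integer(n))
    keepP <- rep(NA_real_, length(cand))
    for (k in seq_along(cand)) {
        b <- cand[k]
        bv <- diamond_values(m, b, window)
        interior <- setdiff(c((edges[k] + 2L):(b - 1L),
                              (b + 2L):(edges[k + 2L] - 1L)),
                            c(cand, 0L, n))
        interior <- interior[interior >= 1L & interior <= n - 1L]
        if (length(interior) < 2) { keepP[k] <- 0; next }
        dv <- unlist(lapply(interior, diamond_values, m = m,
                            window = window))
        keepP[k] <- suppressWarnings(
            wilcox.test(bv, dv, alternative = "less")$p.value)
    }
    keep <- keepP < pThresh
    tadSet(cand[keep], n, chrom(cm), binSize(cm), binSignal = s,
           boundaryP = keepP[keep])
}

#' Directionality index counts
#'
#' For every bin i, \code{up} is the total raw contact count with the
#' preceding \code{span} bins and \code{down} with the following
#' \code{span} bins, truncated at chromosome ends; returned per replicate.
#'
#' @param matrices list of raw replicate \linkS4class{ContactMatrix}
#' @param span window in bins
#' @return list (one per replicate) of data.frame(up, down)
#' @export
directionIndex <- function(matrices, span = 7L) {
    lapply(matrices, function(cm) {
        m <- counts(cm)
        n <- nrow(m)
        up <- down <- numeric(n)
        for (i in seq_len(n)) {
            if (i > 1)
                up[i] <- sum(m[i, max(1L, i - span):(i - 1L)])
            if (i < n)
                down[i] <- sum(m[i, (i + 1L):min(n, i + span)])
        }
        data.frame(up = up, down = down)
    })
}

## inverse-variance pooled log directionality ratio of one condition at bin b
pooled_ldr <- function(di, b) {
    est <- vapply(di, function(d)
        log((d$down[b] + 0.5) / (d$up[b] + 0.5)), numeric(1))
    v <- vapply(di, function(d)
        1 / (d$down[b] + 0.5) + 1 / (d$up[b] + 0.5), numeric(1))
    w <- 1 / v
    c(mean = sum(w * est) / sum(w), var = 1 / sum(w))
}

#' Test boundaries for significant directionality change
#'
#' At every candidate boundary, the log directionality ratio
#' \code{log((down + 0.5) / (up + 0.5))} of the bin left of the boundary is
#' compared between conditions. Replicate estimates are pooled by their
#' count-based (inverse-variance) weights and the conditions compared with
#' a two-sample z statistic; p-values are BH-adjusted across candidates.
#' Reference boundaries absent from the treated set with FDR below the
#' threshold are reported lost; treated-only boundaries, gained.
#'
#' @param diT,di0 directionality-index lists (one data.frame per
#'   replicate) for the treated and baseline condition; at least two
#'   replicates each
#' @param refBoundaries,altBoundaries boundary sets called at baseline and
#'   treated timepoints
#' @param fdr FDR threshold
#' @param timepoint label recorded in the output
#' @return data.frame(boundary, direction, p, fdr, timepoint); one row per
#'   candidate boundary in the union, direction "lost", "gained" or
#'   "stable"
#' @export
testBoundaryChange <- function(diT, di0, refBoundaries, altBoundaries,
                               fdr = 0.05, timepoint = "treated") {
    if (length(diT) < 2 || length(di0) < 2)
        stop("boundary testing requires at least two replicates per condition")
    cand <- sort(union(refBoundaries, altBoundaries))
    if (!length(cand))
        return(data.frame(boundary = integer(), direction = character(),
                          p = numeric(), fdr = numeric(),
                          timepoint = character()))
    pv <- vapply(cand, function(b) {
        a <- pooled_ldr(diT, b)
        z0 <- pooled_ldr(di0, b)
        z <- (a["mean"] - z0["mean"]) / sqrt(a["var"] + z0["var"])
        2 * pnorm(-abs(z))
    }, numeric(1))
    q <- p.adjust(pv, "BH")
    dir <- ifelse(cand %in% refBoundaries & !(cand %in% altBoundaries),
                  "lost",
                  ifelse(cand %in% altBoundaries &
                         !(cand %in% refBoundaries), "gained", "stable"))
    dir[q >= fdr] <- "stable"
    data.frame(boundary = cand, direction = dir, p = pv, fdr = q,
               timepoint = timepoint)
}

#' Classify TAD reorganization events
#'
#' Each significantly lost boundary with a significantly gained boundary
#' within \code{shiftTolBins} forms a shifting event (nearest pairing, ties
#' to the left); remaining lost boundaries merge two reference domains
#' (fusion); remaining gained boundaries split one reference domain
#' (separation). Every significant change belongs to exactly one event.
#'
#' @param ref,alt \linkS4class{TADSet} at baseline and treated timepoints
#' @param changes output of \code{\link{testBoundaryChange}}
#' @param shiftTolBins maximum lost-gained distance for a shift
#' @return list(events data.frame, unchanged count)
#' @export
classifyReorganization <- function(ref, alt, changes, shiftTolBins = 2L) {
    known <- union(boundaries(ref), boundaries(alt))
    if (any(!changes$boundary %in% known))
        stop("change references a bin absent from both boundary sets")
    lost <- changes$boundary[changes$direction == "lost"]
    gained <- changes$boundary[changes$direction == "gained"]
    events <- data.frame(type = character(), lost = integer(),
                         gained = integer())
    usedGain <- integer()
    for (b in sort(lost)) {
        avail <- setdiff(gained, usedGain)
        if (length(avail)) {
            dd <- abs(avail - b)
            if (min(dd) <= shiftTolBins) {
                g <- avail[order(dd, avail)][1]   # nearest, ties to the left
                usedGain <- c(usedGain, g)
                events <- rbind(events, data.frame(type = "shifting",
                    lost = b, gained = g))
                next
            }
        }
        events <- rbind(events, data.frame(type = "fusion", lost = b,
                                           gained = NA_integer_))
    }
    for (g in sort(setdiff(gained, usedGain)))
        events <- rbind(events, data.frame(type = "separation",
                                           lost = NA_integer_, gained = g))
    unchanged <- sum(changes$direction == "stable" &
                     changes$boundary %in% boundaries(ref) &
                     changes$boundary %in% boundaries(alt))
    list(events = events, unchanged = unchanged)
}

## separable bilinear resampling: rows and columns are interpolated with
## the same weight matrix, so resize(sub) = W sub W^T (agrees with
## pracma::interp2 on the same grid; see the unit test)
resize_bilinear <- function(sub, target) {
    n <- nrow(sub)
    if (n == target) return(sub)
    xi <- seq(1, n, length.out = target)
    i0 <- pmin(floor(xi), n - 1L)
    f <- xi - i0
    W <- matrix(0, target, n)
    W[cbind(seq_len(target), i0)] <- 1 - f
    W[cbind(seq_len(target), i0 + 1L)] <- f
    W %*% sub %*% t(W)
}

#' Aggregate TAD analysis
#'
#' Each domain longer than 3 bins is extracted with flanks of
#' \code{flankFrac} times its length on both sides, rescaled by bilinear
#' interpolation to a common grid and averaged. The central block of the
#' grid corresponds to the domain body.
#'
#' @param oeCm an O/E \linkS4class{ContactMatrix}
#' @param tads a \linkS4class{TADSet}
#' @param targetSize body size of the output grid in pixels
#' @param flankFrac flank length as a fraction of domain length
#' @param select optional logical/integer selector of domains
#' @return list(grid, bodyMean, flankMean, intraTadMean, nTads)
#' @export
ata <- function(oeCm, tads, targetSize = 50L, flankFrac = 0.5,
                select = NULL) {
    m <- counts(oeCm)
    n <- nrow(m)
    d <- domains(tads)
    if (!is.null(select)) d <- d[select, , drop = FALSE]
    len <- d[, 2] - d[, 1] + 1L
    d <- d[len > 3L, , drop = FALSE]
    if (!nrow(d)) stop("no domain longer than 3 bins")
    flankPix <- round(targetSize * flankFrac)
    out <- 2L * flankPix + targetSize
    acc <- matrix(0, out, out)
    cnt <- matrix(0, out, out)
    intra <- numeric(0)
    for (t in seq_len(nrow(d))) {
        L <- d[t, 2] - d[t, 1] + 1L
        fl <- round(flankFrac * L)
        lo <- d[t, 1] - fl; hi <- d[t, 2] + fl
        if (lo < 1L || hi > n) next
        sub <- m[lo:hi, lo:hi]
        if (anyNA(sub)) {
            mu <- mean(sub, na.rm = TRUE)
            if (!is.finite(mu)) next
            sub[is.na(sub)] <- mu
        }
        rs <- resize_bilinear(sub, out)
        acc <- acc + rs
        cnt <- cnt + 1
        body <- m[d[t, 1]:d[t, 2], d[t, 1]:d[t, 2]]
        intra <- c(intra, mean(body, na.rm = TRUE))
    }
    if (all(cnt == 0)) stop("no domain fits inside the matrix with flanks")
    grid <- acc / cnt
    bodyIdx <- (flankPix + 1L):(flankPix + targetSize)
    flankMask <- matrix(TRUE, out, out)
    flankMask[bodyIdx, bodyIdx] <- FALSE
    list(grid = grid, bodyMean = mean(grid[bodyIdx, bodyIdx]),
         flankMean = mean(grid[flankMask]),
         intraTadMean = mean(intra), nTads = sum(cnt[1, 1]))
}

#' Match called boundaries to a reference set
#'
#' Precision/recall/F1 with a +/- tolerance, greedy one-to-one matching.
#'
#' @param called,truth boundary bin vectors
#' @param tol matching tolerance in bins
#' @return list(precision, recall, f1, nMatched)
#' @export
boundaryF1 <- function(called, truth, tol = 1L) {
    called <- sort(called); truth <- sort(truth)
    matched <- 0L
    availT <- truth
    for (b in called) {
        dd <- abs(availT - b)
        if (length(availT) && min(dd) <= tol) {
            availT <- availT[-which.min(dd)]
            matched <- matched + 1L
        }
    }
    prec <- if (length(called)) matched / length(called) else NA_real_
    rec <- if (length(truth)) matched / length(truth) else NA_real_
    f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) 0 else
        2 * prec * rec / (prec + rec)
    list(precision = prec, recall = rec, f1 = f1, nMatched = matched)
}
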