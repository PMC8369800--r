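## Depth normalization, ICE balancing, observed/expected transform.

matrix_total <- function(cm) {
    m <- counts(cm)
    sum(m[upper.tri(m, diag = TRUE)])
}

#' Downsample contact matrices to the smallest total
#'
#' Matches sequencing-depth normalization of a multi-condition experiment:
#' every matrix is thinned by sampling contact pairs without replacement
#' (multivariate hypergeometric over cells) down to the smallest total
#' across inputs.
#'
#' @param matrices list of raw \linkS4class{ContactMatrix} on one bin table
#' @param seed RNG seed
#' @return list of downsampled \linkS4class{ContactMatrix}, all with equal
#'   totals
#' @export
downsampleToMin <- function(matrices, seed = 1L) {
    stopifnot(length(matrices) >= 2)
    totals <- vapply(matrices, matrix_total, numeric(1))
    if (any(totals == 0)) stop("cannot downsample an empty matrix")
    target <- min(totals)
    set.seed(seed)
    lapply(matrices, function(cm) {
        m <- counts(cm)
        ut <- upper.tri(m, diag = TRUE)
        v <- m[ut]
        tot <- sum(v)
        if (tot > target) {
            ## multivariate hypergeometric thinning: draw `target` contact
            ## units uniformly without replacement and re-bin them by cell
            u <- sample.int(tot, target)
            cum <- cumsum(v)
            cell <- findInterval(u - 0.5, cum) + 1L
            v <- as.numeric(tabulate(cell, nbins = length(v)))
        }
        m2 <- matrix(0, nrow(m), ncol(m))
        m2[ut] <- v
        m2 <- m2 + t(m2) - diag(diag(m2))
        contactMatrix(m2, chrom = chrom(cm), binSize = binSize(cm))
    })
}

#' ICE balancing of a contact matrix
#'
#' Univariate iterative correction: per-bin biases are updated
#' \code{b_i <- b_i * s_i / mean(s)} where \code{s} are row sums of the
#' rescaled matrix, until the maximum relative deviation of row sums from
#' their mean falls below \code{tol}. Bins whose raw coverage is below the
#' \code{maskQuantile} quantile of nonzero row sums (and all-zero bins) are
#' masked and excluded. The balanced matrix is rescaled to preserve the raw
#' total.
#'
#' @param cm a raw \linkS4class{ContactMatrix}
#' @param maxIter maximum iterations
#' @param tol convergence tolerance on relative row-sum deviation
#' @param maskQuantile low-coverage mask quantile
#' @return a \linkS4class{ContactMatrix} of kind "balanced" with weights
#'   and mask filled
#' @export
iceBalance <- function(cm, maxIter = 200L, tol = 1e-6,
                       maskQuantile = 0.02) {
    m <- counts(cm)
    n <- nrow(m)
    rs <- rowSums(m)
    if (all(rs == 0)) stop("cannot balance an all-zero matrix")
    maskv <- rs == 0
    nzq <- quantile(rs[rs > 0], maskQuantile)
    maskv <- maskv | rs < nzq
    keep <- which(!maskv)
    b <- rep(1, n)
    sub <- m[keep, keep, drop = FALSE]
    bk <- rep(1, length(keep))
    for (it in seq_len(maxIter)) {
        w <- sub / outer(bk, bk)
        s <- rowSums(w)
        sm <- mean(s)
        dev <- max(abs(s / sm - 1))
        if (dev < tol) break
        bk <- bk * s / sm
    }
    bal <- matrix(NA_real_, n, n)
    balSub <- sub / outer(bk, bk)
    ## preserve the raw total over the kept block
    sc <- sum(sub) / sum(balSub)
    bal[keep, keep] <- balSub * sc
    b[keep] <- bk / sqrt(sc)
    b[maskv] <- 0
    new("ContactMatrix", chrom = chrom(cm), binSize = binSize(cm),
        counts = bal, weights = b, mask = maskv, kind = "balanced")
}

## per-distance mean over non-masked pairs; index k+1 holds distance k
expectedByDistance <- function(m, maskv) {
    n <- nrow(m)
    d <- rep(NA_real_, n)
    keep <- !maskv
    for (k in 0:(n - 1)) {
        i <- seq_len(n - k)
        j <- i + k
        ok <- keep[i] & keep[j]
        if (any(ok)) {
            mu <- mean(m[cbind(i[ok], j[ok])])
            if (mu > 0) d[k + 1] <- mu   # all-zero strata stay undefined
        }
    }
    d
}

#' Observed-over-expected transform
#'
#' Divides each balanced contact value by the mean balanced value over all
#' non-masked pairs at the same genomic distance on the chromosome, so the
#' per-distance mean of the result is exactly 1.
#'
#' @param cm a balanced \linkS4class{ContactMatrix}
#' @return a \linkS4class{ContactMatrix} of kind "oe"
#' @export
oeTransform <- function(cm) {
    if (matrixKind(cm) != "balanced")
        stop("oeTransform expects a balanced matrix (run iceBalance first)")
    m <- counts(cm)
    n <- nrow(m)
    maskv <- mask(cm)
    d <- expectedByDistance(m, maskv)
    dist <- abs(outer(seq_len(n), seq_len(n), "-"))
    oe <- m / matrix(d[dist + 1], n, n)
    oe[maskv, ] <- NA_real_
    oe[, maskv] <- NA_real_
    new("ContactMatrix", chrom = chrom(cm), binSize = binSize(cm),
        counts = oe, weights = weights(cm), mask = maskv, kind = "oe")
}

#' Merge replicate contact matrices by summing counts
#' @param matrices list of raw \linkS4class{ContactMatrix}
#' @return a raw \linkS4class{ContactMatrix}
#' @export
mergeReplicates <- function(matrices) {
    m <- Reduce(`+`, lapply(matrices, counts))
    contactMatrix(m, chrom = chrom(matrices[[1]]),
                  binSize = binSize(matrices[[1]]))
}
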