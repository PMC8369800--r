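## Signal-track enrichment statistics: fold enrichment of a binned signal
## in interval sets, pseudo-cluster Spearman correlation, region-vs-rest
## rank-sum tests, and peak density around classified TAD boundaries.

region_bins <- function(track, regions) {
    binsInRegions(regions, nbins(track), binSize(track), chrom(track))
}

#' Fold enrichment of a signal in regions
#'
#' Median signal of bins intersecting the regions (any-overlap rule)
#' divided by the median over all bins; zero-signal bins are included.
#'
#' @param track a \linkS4class{SignalTrack}
#' @param regions a \code{GRanges}
#' @return fold enrichment (NA with a warning when the genome median is 0)
#' @export
foldEnrichment <- function(track, regions) {
    v <- trackValues(track)
    inb <- region_bins(track, regions)
    gm <- median(v)
    if (gm == 0) {
        warning("genome-wide median signal is zero; fold enrichment undefined")
        return(NA_real_)
    }
    median(v[inb]) / gm
}

#' Pseudo-cluster Spearman correlation
#'
#' Spearman correlation between the binned signal and a +1/-1 indicator of
#' region membership.
#'
#' @inheritParams foldEnrichment
#' @return Spearman rho
#' @export
pseudoClusterCorrelation <- function(track, regions) {
    v <- trackValues(track)
    ind <- rep(-1, length(v))
    ind[region_bins(track, regions)] <- 1
    suppressWarnings(cor(v, ind, method = "spearman"))
}

#' Rank-sum test of in-region versus out-of-region signal
#'
#' @inheritParams foldEnrichment
#' @return two-sided Wilcoxon rank-sum p-value
#' @export
regionVsRestTest <- function(track, regions) {
    v <- trackValues(track)
    inb <- region_bins(track, regions)
    if (!length(inb) || length(inb) == length(v))
        stop("both groups must be non-empty")
    suppressWarnings(wilcox.test(v[inb], v[-inb])$p.value)
}

#' Peak density around classified boundaries
#'
#' Peaks are assigned to bins by their midpoint; the profile holds, per
#' boundary class, the mean peak count per bin at each offset within
#' \code{flankBins} of the boundary bin.
#'
#' @param peaks a \code{GRanges} of peaks
#' @param boundaryBins boundary bin indices
#' @param classes per-boundary class labels (e.g. unchanged/lost/gained)
#' @param nBins,binSize,chromName bin table of the chromosome
#' @param flankBins half-width of the profile in bins
#' @return matrix (class x offset) of mean peak counts per bin
#' @export
boundaryPeakDensity <- function(peaks, boundaryBins, classes, nBins,
                                binSize, chromName = "chrS",
                                flankBins = 5L) {
    stopifnot(length(boundaryBins) == length(classes))
    peakBin <- floor(((start(peaks) + end(peaks)) / 2 - 1) / binSize) + 1
    peakCount <- tabulate(peakBin[peakBin >= 1 & peakBin <= nBins], nBins)
    offsets <- -flankBins:flankBins
    ucls <- sort(unique(classes))
    out <- matrix(0, length(ucls), length(offsets),
                  dimnames = list(ucls, offsets))
    for (cl in ucls) {
        bs <- boundaryBins[classes == cl]
        for (o in seq_along(offsets)) {
            pos <- bs + offsets[o]
            ok <- pos >= 1 & pos <= nBins
            out[cl, o] <- if (any(ok)) mean(peakCount[pos[ok]]) else 0
        }
    }
    out
}
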