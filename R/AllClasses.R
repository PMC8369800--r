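#' @import methods
#' @importFrom stats cor median p.adjust phyper pnorm quantile rnorm rpois
#'   runif sd t.test var wilcox.test lm coef rhyper setNames aggregate
#' @importFrom utils head tail read.table write.table
NULL

## Central S4 data model. One ContactMatrix per chromosome; all analyses are
## cis, per chromosome.

#' Simulation configuration
#'
#' Parameters of the synthetic Hi-C generator: a power-law distance decay
#' modulated by a planted compartment eigenprofile, TAD blocks and loop
#' anchors, observed through Poisson counting noise at a given sequencing
#' depth.
#'
#' @slot nBins number of bins on the simulated chromosome (>= 50)
#' @slot binSize bin width in bp
#' @slot decayExponent alpha in P(s) ~ s^-alpha
#' @slot compartmentAmplitude c in exp(c * e_i * e_j)
#' @slot tadBoost multiplicative boost for intra-TAD contacts (>= 1)
#' @slot loopBoost multiplicative boost at planted anchor pairs +/- 1 bin
#' @slot depth expected total contact count per replicate
#' @slot nReplicates number of Poisson replicates sharing one intensity
#' @slot seed RNG seed
#' @export
setClass("SimConfig", representation(
    nBins = "integer", binSize = "numeric", decayExponent = "numeric",
    compartmentAmplitude = "numeric", tadBoost = "numeric",
    loopBoost = "numeric", depth = "numeric", nReplicates = "integer",
    seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nBins < 50L) msg <- c(msg, "nBins must be >= 50")
    if (object@decayExponent <= 0) msg <- c(msg, "decayExponent must be > 0")
    if (object@depth <= 0) msg <- c(msg, "depth must be > 0")
    if (object@tadBoost < 1 || object@loopBoost < 1)
        msg <- c(msg, "boosts must be >= 1")
    if (object@binSize <= 0) msg <- c(msg, "binSize must be > 0")
    if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults describe one 20 Mb synthetic chromosome binned at 40 kb, with a
#' unit decay exponent, unit compartment amplitude, 2x intra-TAD boost, 3x
#' loop boost and two replicates of one million contacts each.
#'
#' @param nBins,binSize,decayExponent,compartmentAmplitude,tadBoost,loopBoost
#'   see \linkS4class{SimConfig}
#' @param depth,nReplicates,seed see \linkS4class{SimConfig}
#' @return a \linkS4class{SimConfig}
#' @examples
#' simConfig(nBins = 100, seed = 1)
#' @export
simConfig <- function(nBins = 500L, binSize = 40000, decayExponent = 1.0,
                      compartmentAmplitude = 1.0, tadBoost = 2.0,
                      loopBoost = 3.0, depth = 1e6, nReplicates = 2L,
                      seed = 1L) {
    new("SimConfig", nBins = as.integer(nBins), binSize = binSize,
        decayExponent = decayExponent,
        compartmentAmplitude = compartmentAmplitude, tadBoost = tadBoost,
        loopBoost = loopBoost, depth = depth,
        nReplicates = as.integer(nReplicates), seed = as.integer(seed))
}

#' Planted ground truth of a simulated chromosome
#'
#' @slot trueProfile per-bin compartment eigenprofile e_i
#' @slot trueBoundaries sorted TAD boundary bins (boundary b sits between
#'   bins b and b+1)
#' @slot loopAnchors two-column matrix of anchor bin pairs (i < j)
#' @slot switchRegions data.frame of planted compartment-switch regions
#'   (columns start, end, onset, recoverable, label), empty for single
#'   timepoints
#' @slot params list of generator / perturbation parameters actually used
#' @export
setClass("PlantedTruth", representation(
    trueProfile = "numeric", trueBoundaries = "integer",
    loopAnchors = "matrix", switchRegions = "data.frame", params = "list"))

setValidity("PlantedTruth", function(object) {
    n <- length(object@trueProfile)
    b <- object@trueBoundaries
    msg <- character()
    if (is.unsorted(b, strictly = TRUE)) msg <- c(msg, "boundaries must be strictly increasing")
    if (length(b) && (min(b) < 1L || max(b) > n - 1L))
        msg <- c(msg, "boundaries must lie in [1, nBins-1]")
    la <- object@loopAnchors
    if (nrow(la) && any(la[, 1] >= la[, 2]))
        msg <- c(msg, "loop anchors must have i < j")
    if (length(msg)) msg else TRUE
})

#' Binned cis contact map for one chromosome
#'
#' Stores a dense symmetric matrix of contact values together with ICE
#' balancing weights and a mask of excluded (low-coverage) bins. The
#' \code{kind} slot records whether \code{counts} holds raw counts, balanced
#' values or observed/expected values.
#'
#' @slot chrom chromosome name
#' @slot binSize bin width in bp
#' @slot counts symmetric matrix of contact values
#' @slot weights per-bin ICE weights (NA until balanced; 0 for masked bins)
#' @slot mask logical, TRUE for excluded bins
#' @slot kind one of "raw", "balanced", "oe"
#' @export
setClass("ContactMatrix", representation(
    chrom = "character", binSize = "numeric", counts = "matrix",
    weights = "numeric", mask = "logical", kind = "character"))

setValidity("ContactMatrix", function(object) {
    m <- object@counts
    msg <- character()
    if (nrow(m) != ncol(m)) msg <- c(msg, "counts must be square")
    if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE)))
        msg <- c(msg, "counts must be symmetric")
    if (any(m < 0, na.rm = TRUE)) msg <- c(msg, "counts must be non-negative")
    if (length(object@weights) != nrow(m) || length(object@mask) != nrow(m))
        msg <- c(msg, "weights and mask must have one entry per bin")
    if (object@binSize <= 0) msg <- c(msg, "binSize must be > 0")
    if (!object@kind %in% c("raw", "balanced", "oe"))
        msg <- c(msg, "kind must be raw, balanced or oe")
    if (any(object@mask & !is.na(object@weights) & object@weights != 0))
        msg <- c(msg, "masked bins must have zero weight")
    if (length(msg)) msg else TRUE
})

#' Construct a ContactMatrix
#'
#' @param counts symmetric non-negative matrix (or upper triangle; mirrored)
#' @param chrom chromosome name
#' @param binSize bin width in bp
#' @param weights optional per-bin balancing weights
#' @param mask optional logical exclusion mask
#' @param kind "raw" (default), "balanced" or "oe"
#' @return a \linkS4class{ContactMatrix}
#' @export
contactMatrix <- function(counts, chrom = "chrS", binSize = 40000,
                          weights = NULL, mask = NULL, kind = "raw") {
    counts <- as.matrix(counts)
    lt <- lower.tri(counts)
    counts[lt] <- t(counts)[lt]  # upper triangle is canonical if asymmetric
    n <- nrow(counts)
    if (is.null(weights)) weights <- rep(NA_real_, n)
    if (is.null(mask)) mask <- rep(FALSE, n)
    weights[mask & !is.na(weights)] <- 0
    new("ContactMatrix", chrom = chrom, binSize = binSize, counts = counts,
        weights = weights, mask = mask, kind = kind)
}

#' Per-bin compartment profile for one timepoint
#'
#' @slot chrom chromosome name
#' @slot binSize bin width in bp
#' @slot pc1 per-bin leading-eigenvector value (NA on filtered bins)
#' @slot label per-bin compartment label "A", "B" or "filtered"
#' @slot strength per-bin compartment strength (NA until computed)
#' @slot timepoint timepoint name
#' @slot eigenvalueFraction share of total correlation captured by PC1
#' @slot lowConfidence TRUE when the leading eigenvalue is too small for a
#'   trustworthy A/B partition
#' @export
setClass("CompartmentProfile", representation(
    chrom = "character", binSize = "numeric", pc1 = "numeric",
    label = "character", strength = "numeric", timepoint = "character",
    eigenvalueFraction = "numeric", lowConfidence = "logical"))

setValidity("CompartmentProfile", function(object) {
    msg <- character()
    if (length(object@label) != length(object@pc1))
        msg <- c(msg, "label and pc1 lengths differ")
    if (!all(object@label %in% c("A", "B", "filtered")))
        msg <- c(msg, "labels must be A, B or filtered")
    ok <- object@label != "filtered"
    if (any(ok & is.na(object@pc1)))
        msg <- c(msg, "non-filtered bins must carry a pc1 value")
    if (any((object@pc1[ok] > 0) != (object@label[ok] == "A")))
        msg <- c(msg, "label A must correspond to pc1 > 0")
    if (length(msg)) msg else TRUE
})

#' Ordered TAD partition of one chromosome
#'
#' Domains tile the chromosome; \code{boundaries} are the shared interior
#' endpoints (boundary b separates bins b and b+1).
#'
#' @slot chrom chromosome name
#' @slot binSize bin width in bp
#' @slot nBins number of bins
#' @slot domains two-column matrix (start, end) of inclusive bin intervals
#' @slot boundaries sorted interior boundary bins
#' @slot binSignal per-boundary-position diamond mean signal
#' @slot boundaryP per-boundary filter p-value
#' @export
setClass("TADSet", representation(
    chrom = "character", binSize = "numeric", nBins = "integer",
    domains = "matrix", boundaries = "integer", binSignal = "numeric",
    boundaryP = "numeric"))

setValidity("TADSet", function(object) {
    d <- object@domains
    msg <- character()
    if (ncol(d) != 2L) msg <- c(msg, "domains must have two columns")
    if (nrow(d)) {
        if (d[1, 1] != 1L || d[nrow(d), 2] != object@nBins)
            msg <- c(msg, "domains must tile [1, nBins]")
        if (nrow(d) > 1 && any(d[-1, 1] != d[-nrow(d), 2] + 1L))
            msg <- c(msg, "domains must be contiguous and non-overlapping")
        if (!identical(as.integer(object@boundaries),
                       as.integer(d[-nrow(d), 2])))
            msg <- c(msg, "boundaries must equal shared domain endpoints")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a TADSet from interior boundary bins
#'
#' @param boundaries interior boundary bins (deduplicated, sorted, clipped
#'   to [1, nBins - 1])
#' @param nBins chromosome length in bins
#' @param chrom,binSize metadata
#' @param binSignal,boundaryP optional per-position diamond signal and
#'   per-boundary p-values
#' @return a \linkS4class{TADSet} whose domains tile the chromosome
#' @export
tadSet <- function(boundaries, nBins, chrom = "chrS", binSize = 40000,
                   binSignal = numeric(), boundaryP = numeric()) {
    boundaries <- sort(as.integer(unique(boundaries)))
    boundaries <- boundaries[boundaries >= 1L & boundaries <= nBins - 1L]
    starts <- c(1L, boundaries + 1L)
    ends <- c(boundaries, as.integer(nBins))
    new("TADSet", chrom = chrom, binSize = binSize, nBins = as.integer(nBins),
        domains = cbind(start = starts, end = ends), boundaries = boundaries,
        binSignal = binSignal,
        boundaryP = if (length(boundaryP)) boundaryP else
            rep(NA_real_, length(boundaries)))
}

#' Binned signal track for one chromosome
#'
#' @slot chrom chromosome name
#' @slot binSize bin width in bp
#' @slot values per-bin signal (any real value, e.g. occupancy or PC1)
#' @export
setClass("SignalTrack", representation(
    chrom = "character", binSize = "numeric", values = "numeric"))

setValidity("SignalTrack", function(object) {
    if (length(object@values) == 0)
        "signal track must contain at least one bin" else TRUE
})

signalTrack <- function(values, chrom = "chrS", binSize = 40000) {
    new("SignalTrack", chrom = chrom, binSize = binSize,
        values = as.numeric(values))
}
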