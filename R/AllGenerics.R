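#' @importFrom BiocGenerics counts
NULL

#' Accessors for HiCflux data objects
#'
#' \code{counts} returns the contact value matrix (raw, balanced or O/E
#' according to \code{matrixKind}); \code{chrom}, \code{binSize},
#' \code{nbins}, \code{weights} and \code{mask} return the corresponding
#' slots; \code{pc1} and \code{compartmentLabels} access a
#' \linkS4class{CompartmentProfile}; \code{domains} and \code{boundaries}
#' access a \linkS4class{TADSet}; \code{trackValues} accesses a
#' \linkS4class{SignalTrack}.
#'
#' @param object,x a HiCflux data object
#' @return the slot value
#' @name accessors
#' @aliases counts,ContactMatrix-method
NULL

#' @rdname accessors
#' @export
setGeneric("chrom", function(object) standardGeneric("chrom"))
#' @rdname accessors
#' @export
setGeneric("binSize", function(object) standardGeneric("binSize"))
#' @rdname accessors
#' @export
setGeneric("nbins", function(object) standardGeneric("nbins"))
#' @rdname accessors
#' @importFrom stats weights
#' @export
setGeneric("weights")
#' @rdname accessors
#' @export
setGeneric("mask", function(object) standardGeneric("mask"))
#' @rdname accessors
#' @export
setGeneric("matrixKind", function(object) standardGeneric("matrixKind"))
#' @rdname accessors
#' @export
setGeneric("pc1", function(object) standardGeneric("pc1"))
#' @rdname accessors
#' @export
setGeneric("compartmentLabels",
           function(object) standardGeneric("compartmentLabels"))
#' @rdname accessors
#' @export
setGeneric("domains", function(object) standardGeneric("domains"))
#' @rdname accessors
#' @export
setGeneric("boundaries", function(object) standardGeneric("boundaries"))
#' @rdname accessors
#' @export
setGeneric("trackValues", function(object) standardGeneric("trackValues"))
#' @rdname accessors
#' @export
setGeneric("trueProfile", function(object) standardGeneric("trueProfile"))
#' @rdname accessors
#' @export
setGeneric("trueBoundaries",
           function(object) standardGeneric("trueBoundaries"))
#' @rdname accessors
#' @export
setGeneric("loopAnchors", function(object) standardGeneric("loopAnchors"))

#' @rdname accessors
#' @export
setMethod("counts", "ContactMatrix", function(object) object@counts)
#' @rdname accessors
#' @export
setMethod("chrom", "ContactMatrix", function(object) object@chrom)
#' @rdname accessors
#' @export
setMethod("chrom", "CompartmentProfile", function(object) object@chrom)
#' @rdname accessors
#' @export
setMethod("chrom", "TADSet", function(object) object@chrom)
#' @rdname accessors
#' @export
setMethod("chrom", "SignalTrack", function(object) object@chrom)
#' @rdname accessors
#' @export
setMethod("binSize", "ContactMatrix", function(object) object@binSize)
#' @rdname accessors
#' @export
setMethod("binSize", "CompartmentProfile", function(object) object@binSize)
#' @rdname accessors
#' @export
setMethod("binSize", "TADSet", function(object) object@binSize)
#' @rdname accessors
#' @export
setMethod("binSize", "SignalTrack", function(object) object@binSize)
#' @rdname accessors
#' @export
setMethod("nbins", "ContactMatrix", function(object) nrow(object@counts))
#' @rdname accessors
#' @export
setMethod("nbins", "CompartmentProfile", function(object) length(object@pc1))
#' @rdname accessors
#' @export
setMethod("nbins", "TADSet", function(object) object@nBins)
#' @rdname accessors
#' @export
setMethod("nbins", "SignalTrack", function(object) length(object@values))
#' @rdname accessors
#' @export
setMethod("weights", "ContactMatrix", function(object, ...) object@weights)
#' @rdname accessors
#' @export
setMethod("mask", "ContactMatrix", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("matrixKind", "ContactMatrix", function(object) object@kind)
#' @rdname accessors
#' @export
setMethod("pc1", "CompartmentProfile", function(object) object@pc1)
#' @rdname accessors
#' @export
setMethod("compartmentLabels", "CompartmentProfile",
          function(object) object@label)
#' @rdname accessors
#' @export
setMethod("domains", "TADSet", function(object) object@domains)
#' @rdname accessors
#' @export
setMethod("boundaries", "TADSet", function(object) object@boundaries)
#' @rdname accessors
#' @export
setMethod("trackValues", "SignalTrack", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("trueProfile", "PlantedTruth", function(object) object@trueProfile)
#' @rdname accessors
#' @export
setMethod("trueBoundaries", "PlantedTruth",
          function(object) object@trueBoundaries)
#' @rdname accessors
#' @export
setMethod("loopAnchors", "PlantedTruth", function(object) object@loopAnchors)

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nBins, "bins x", object@binSize, "bp,",
        "alpha =", object@decayExponent,
        "amp =", object@compartmentAmplitude, "\n",
        " tadBoost =", object@tadBoost, "loopBoost =", object@loopBoost,
        "depth =", format(object@depth, big.mark = ","),
        "replicates =", object@nReplicates, "seed =", object@seed, "\n")
})

setMethod("show", "ContactMatrix", function(object) {
    cat("ContactMatrix (", object@kind, ") ", object@chrom, ": ",
        nrow(object@counts), " bins x ", object@binSize, " bp, total = ",
        format(round(sum(object@counts[upper.tri(object@counts, diag = TRUE)],
                         na.rm = TRUE), 1), big.mark = ","),
        ", masked bins = ", sum(object@mask), "\n", sep = "")
})

setMethod("show", "CompartmentProfile", function(object) {
    tab <- table(factor(object@label, c("A", "B", "filtered")))
    cat("CompartmentProfile ", object@chrom, " [", object@timepoint, "]: ",
        length(object@pc1), " bins (A = ", tab[["A"]], ", B = ", tab[["B"]],
        ", filtered = ", tab[["filtered"]], ")",
        if (object@lowConfidence) " [low confidence]", "\n", sep = "")
})

setMethod("show", "TADSet", function(object) {
    cat("TADSet ", object@chrom, ": ", nrow(object@domains), " domains, ",
        length(object@boundaries), " interior boundaries, median size ",
        median((object@domains[, 2] - object@domains[, 1] + 1)) *
            object@binSize / 1000, " kb\n", sep = "")
})

setMethod("show", "PlantedTruth", function(object) {
    cat("PlantedTruth:", length(object@trueProfile), "bins,",
        length(object@trueBoundaries), "TAD boundaries,",
        nrow(object@loopAnchors), "loop anchors,",
        nrow(object@switchRegions), "switch regions\n")
})

setMethod("show", "SignalTrack", function(object) {
    cat("SignalTrack ", object@chrom, ": ", length(object@values),
        " bins x ", object@binSize, " bp\n", sep = "")
})

#' Switch-region table of a planted truth
#' @param truth a \linkS4class{PlantedTruth}
#' @return data.frame of planted switch regions
#' @export
switchRegions <- function(truth) truth@switchRegions

#' Generator/perturbation parameters recorded in a planted truth
#' @param truth a \linkS4class{PlantedTruth}
#' @return named list
#' @export
truthParams <- function(truth) truth@params
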