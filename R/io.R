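## Text I/O: gzip triplet contact matrices with a BED bin table, bedGraph
## signal tracks, BED interval sets, JSON truth sidecars. Coordinates are
## 0-based half-open BED throughout; bin i (1-based index) covers
## [(i-1)*binSize, i*binSize).

#' @importFrom GenomicRanges GRanges seqnames start end width mcols
#'   findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom rtracklayer import export
NULL

#' Bin table of a contact matrix or track
#'
#' @param object a \linkS4class{ContactMatrix}, \linkS4class{SignalTrack} or
#'   \linkS4class{CompartmentProfile}
#' @return \code{GRanges} with one range per bin, 1-based closed as GRanges
#'   convention (bin i covers BED interval [(i-1)*binSize, i*binSize))
#' @export
binTable <- function(object) {
    n <- nbins(object)
    bs <- binSize(object)
    GRanges(chrom(object),
            IRanges(start = (seq_len(n) - 1L) * bs + 1L, width = bs))
}

#' Write / read a contact matrix as gzip triplet text
#'
#' Triplets are \code{bin_i<TAB>bin_j<TAB>count} with 1-based bin indices
#' and i <= j (upper triangle); reading mirrors either triangle into a
#' symmetric matrix. A BED bin table written alongside
#' (\code{\link{writeBinTable}}) defines the coordinates.
#'
#' @param cm a \linkS4class{ContactMatrix}
#' @param path output path (".gz" gets gzip compression)
#' @return \code{writeTriplets} returns \code{path} invisibly
#' @export
writeTriplets <- function(cm, path) {
    m <- counts(cm)
    ut <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
    df <- data.frame(i = ut[, 1], j = ut[, 2], count = m[ut])
    df <- df[order(df$i, df$j), ]
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' @rdname writeTriplets
#' @param path path to a triplet file
#' @param nBins number of bins (from the bin table)
#' @param chrom,binSize matrix metadata
#' @return \code{readTriplets} returns a \linkS4class{ContactMatrix}
#' @export
readTriplets <- function(path, nBins, chrom = "chrS", binSize = 40000) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
    on.exit(close(con))
    lines <- readLines(con)
    lines <- lines[nzchar(lines)]
    m <- matrix(0, nBins, nBins)
    if (length(lines)) {
        parts <- strsplit(lines, "\t", fixed = TRUE)
        bad <- which(lengths(parts) != 3L)
        if (length(bad))
            stop("malformed triplet line ", bad[1], " in ", path)
        rec <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                      ncol = 3, byrow = TRUE)
        bad <- which(apply(is.na(rec), 1, any))
        if (length(bad))
            stop("malformed triplet line ", bad[1], " in ", path)
        if (any(rec[, 1] < 1 | rec[, 1] > nBins |
                rec[, 2] < 1 | rec[, 2] > nBins))
            stop("bin index out of range in ", path)
        if (any(rec[, 3] < 0)) stop("negative count in ", path)
        i <- pmin(rec[, 1], rec[, 2])
        j <- pmax(rec[, 1], rec[, 2])
        m[cbind(i, j)] <- m[cbind(i, j)] + rec[, 3]
        m[cbind(j, i)] <- m[cbind(i, j)]
    }
    contactMatrix(m, chrom = chrom, binSize = binSize)
}

#' Write a BED bin table for a matrix or track
#' @param object object with a bin table
#' @param path output BED path
#' @export
writeBinTable <- function(object, path) {
    gr <- binTable(object)
    export(gr, path, format = "BED")
    invisible(path)
}

#' Write / read a per-bin signal as bedGraph
#' @param track a \linkS4class{SignalTrack} (or
#'   \linkS4class{CompartmentProfile}, whose pc1 is written)
#' @param path bedGraph path
#' @export
writeBedGraph <- function(track, path) {
    gr <- binTable(track)
    v <- if (is(track, "CompartmentProfile")) pc1(track) else
        trackValues(track)
    gr$score <- ifelse(is.na(v), 0, v)
    export(gr, path, format = "bedGraph")
    invisible(path)
}

#' @rdname writeBedGraph
#' @param binSize expected bin width
#' @return \code{readBedGraph} returns a \linkS4class{SignalTrack}
#' @export
readBedGraph <- function(path, binSize = 40000) {
    gr <- import(path, format = "bedGraph")
    gr <- sort(gr)
    signalTrack(gr$score, chrom = as.character(seqnames(gr))[1],
                binSize = binSize)
}

#' Write an interval set (regions, peaks, TADs) as BED
#' @param gr a \code{GRanges}; the \code{name} metadata column, when
#'   present, is kept
#' @param path BED path
#' @export
writeBed <- function(gr, path) {
    export(gr, path, format = "BED")
    invisible(path)
}

#' Read a BED interval set
#' @param path BED path
#' @return \code{GRanges}
#' @export
readBed <- function(path) import(path, format = "BED")

#' Write / read a planted truth sidecar as JSON
#' @param truth a \linkS4class{PlantedTruth}
#' @param path JSON path
#' @export
writePlantedTruth <- function(truth, path) {
    obj <- list(trueProfile = truth@trueProfile,
                trueBoundaries = truth@trueBoundaries,
                loopAnchors = truth@loopAnchors,
                switchRegions = truth@switchRegions)
    jsonlite::write_json(obj, path, digits = NA)
    invisible(path)
}

#' @rdname writePlantedTruth
#' @return \code{readPlantedTruth} returns a \linkS4class{PlantedTruth}
#' @export
readPlantedTruth <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    la <- obj$loopAnchors
    if (is.null(dim(la))) la <- matrix(la, ncol = 2)
    colnames(la) <- c("i", "j")
    sw <- as.data.frame(obj$switchRegions)
    new("PlantedTruth", trueProfile = as.numeric(obj$trueProfile),
        trueBoundaries = as.integer(obj$trueBoundaries),
        loopAnchors = la, switchRegions = sw, params = list())
}

## bins (1-based indices) intersecting any interval of a GRanges, under the
## any-overlap rule
binsInRegions <- function(regions, nBins, binSize, chromName) {
    bins <- GRanges(chromName,
                    IRanges(start = (seq_len(nBins) - 1L) * binSize + 1L,
                            width = binSize))
    unique(queryHits(findOverlaps(bins, regions)))
}
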