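## Shared test helpers: small constructors used across test files.

## wrap a plain matrix as an O/E ContactMatrix without running the full
## balance -> O/E stack (for analytic fixtures)
oeMatrix <- function(m, binSize = 40000, mask = NULL) {
    n <- nrow(m)
    if (is.null(mask)) mask <- rep(FALSE, n)
    new("ContactMatrix", chrom = "chrS", binSize = binSize, counts = m,
        weights = rep(1, n), mask = mask, kind = "oe")
}

## CompartmentProfile directly from a numeric profile (A = positive)
profileFromValues <- function(e, timepoint = "0", binSize = 40000) {
    new("CompartmentProfile", chrom = "chrS", binSize = binSize,
        pc1 = as.numeric(e), label = ifelse(e > 0, "A", "B"),
        strength = rep(NA_real_, length(e)), timepoint = timepoint,
        eigenvalueFraction = 1, lowConfidence = FALSE)
}

## z-score with NA removal (profile comparison on a common scale)
zscore <- function(v) (v - mean(v, na.rm = TRUE)) / sd(v, na.rm = TRUE)

## a schedule with every perturbation switched off except the ones given
bareSchedule <- function(timepoints = c("0", "2"), attenuation = NULL,
                         ampMultiplier = NULL, homogenize = NULL,
                         loopAttenuation = NULL, tadEvents = NULL) {
    k <- length(timepoints)
    perturbationSchedule(
        timepoints = timepoints,
        attenuation = if (is.null(attenuation)) rep(1, k) else attenuation,
        ampMultiplier = if (is.null(ampMultiplier)) rep(1, k) else
            ampMultiplier,
        homogenize = if (is.null(homogenize)) rep(0, k) else homogenize,
        loopAttenuation = if (is.null(loopAttenuation)) rep(1, k) else
            loopAttenuation,
        switches = data.frame(onset = character(), recoverable = logical()),
        tadEvents = if (is.null(tadEvents))
            data.frame(timepoint = character(), type = character(),
                       n = integer()) else tadEvents)
}
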