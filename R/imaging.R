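## Imaging statistics: Ripley's K and L functions for point patterns and
## mean squared displacement of tracked particles.

#' Ripley's K function
#'
#' Exact evaluation of the estimator
#' \deqn{K(r) = (S / (N - 1)) (1/N) \sum_i \sum_{j \ne i} [r_{ij} \le r]}
#' with no edge correction; near the window boundary the estimate is
#' biased low (see the methods vignette), so calibration against complete
#' spatial randomness should use interior radii.
#'
#' @param pattern list with \code{points} (n x 2 matrix) and \code{areaS},
#'   e.g. from \code{\link{simulatePointPattern}}
#' @param radii positive increasing radii
#' @return numeric K(r), non-decreasing
#' @export
ripleyK <- function(pattern, radii) {
    pts <- pattern$points
    N <- nrow(pts)
    if (N < 2) stop("Ripley's K needs at least 2 points")
    stopifnot(all(radii > 0), !is.unsorted(radii))
    dd <- as.matrix(dist(pts))
    dv <- dd[upper.tri(dd)]
    ## each unordered pair contributes twice to the ordered double sum
    vapply(radii, function(r)
        pattern$areaS / (N - 1) / N * 2 * sum(dv <= r), numeric(1))
}

#' Ripley's L function
#' @param K K(r) values
#' @return \code{sqrt(K / pi)}
#' @export
ripleyL <- function(K) {
    stopifnot(all(K >= 0))
    sqrt(K / pi)
}

#' Mean squared displacement of trajectories
#'
#' For each lag, averages squared displacements over particles and all
#' overlapping start frames; the 3D estimate is 1.5 times the observed 2D
#' value (isotropy assumption for motion observed in a 2D plane).
#'
#' @param trajectories data.frame(particle, frame, x, y) with attribute
#'   \code{dt} (or pass \code{dt})
#' @param maxLag maximum lag in frames (must be shorter than the shortest
#'   trajectory)
#' @param dt frame interval; defaults to the data.frame attribute
#' @return data.frame(lag, tau, msd2d, msd3d)
#' @export
msd <- function(trajectories, maxLag, dt = attr(trajectories, "dt")) {
    if (!nrow(trajectories)) stop("empty trajectory set")
    if (is.null(dt)) stop("frame interval dt unknown")
    byP <- split(trajectories[, c("x", "y")], trajectories$particle)
    shortest <- min(vapply(byP, nrow, integer(1)))
    if (maxLag >= shortest)
        stop("maxLag must be below the shortest trajectory length")
    m2 <- vapply(seq_len(maxLag), function(l) {
        num <- 0; den <- 0
        for (tr in byP) {
            n <- nrow(tr)
            dx <- tr$x[(1 + l):n] - tr$x[1:(n - l)]
            dy <- tr$y[(1 + l):n] - tr$y[1:(n - l)]
            num <- num + sum(dx^2 + dy^2)
            den <- den + (n - l)
        }
        num / den
    }, numeric(1))
    data.frame(lag = 0:maxLag, tau = (0:maxLag) * dt,
               msd2d = c(0, m2), msd3d = 1.5 * c(0, m2))
}

#' Diffusion coefficient from an MSD curve
#'
#' Least-squares slope of the 2D MSD over the first \code{nLags} positive
#' lags divided by 4; a constant localization-noise offset is absorbed by
#' the intercept.
#'
#' @param curve data.frame from \code{\link{msd}}
#' @param nLags number of positive lags to fit
#' @return estimated D
#' @export
fitDiffusion <- function(curve, nLags = 4L) {
    pos <- curve[curve$lag > 0, ]
    if (nrow(pos) < nLags) stop("need at least nLags positive lags")
    fit <- lm(msd2d ~ tau, data = pos[seq_len(nLags), ])
    unname(coef(fit)[2] / 4)
}
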