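## Locus-specific Southern zero-class analysis and generic normalized
## band-ratio quantification for western/northern blots.

#' Intact-fragment (zero-class) fraction from a band pair
#'
#' The restriction digest is split into two equal aliquots, one treated
#' with the lesion-cleaving enzymes and one mock-treated, so the intact
#' fraction is the ratio of full-length band signals
#' \code{P0 = signal(+enzyme) / signal(-enzyme)}. Blot noise routinely
#' produces ratios slightly above 1; ratios in (1, 1 + tol] are clamped to
#' 1 with a QC flag, while larger ratios indicate pairing or loading errors
#' and raise an error.
#'
#' @param bandPlus,bandMinus Band volumes of the enzyme-treated and control
#'   aliquot (non-negative; control must be positive).
#' @param tol Clamp window above 1 (default 0.05).
#' @return P0 in (0, 1], with logical attribute \code{"qcClamped"}.
#' @examples
#' zeroClassFraction(36.79, 100)   # 0.3679, mu ~ 1
#' zeroClassFraction(103, 100)     # clamped to 1
#' @export
zeroClassFraction <- function(bandPlus, bandMinus, tol = 0.05) {
    stopifnot(is.numeric(bandPlus), is.numeric(bandMinus),
              length(bandPlus) == length(bandMinus), tol >= 0)
    if (any(!is.finite(bandMinus) | bandMinus <= 0))
        stop("control (no-enzyme) band signal must be positive")
    if (any(!is.finite(bandPlus) | bandPlus < 0))
        stop("band signals must be non-negative")
    p0 <- bandPlus / bandMinus
    over <- p0 > 1 + tol
    if (any(over))
        stop(sprintf(
            "band ratio %s exceeds 1 + %g: check lane pairing/loading",
            paste(format(p0[over]), collapse = ", "), tol))
    clamped <- p0 > 1
    p0[clamped] <- 1
    attr(p0, "qcClamped") <- clamped
    p0
}

#' Restriction-fragment repair time course by the zero-class method
#'
#' Converts a series of (+enzyme, -enzyme) band pairs into a repair curve:
#' \code{P0(t)} from each pair, \code{mu(t) = -ln(P0(t))}, percent repair
#' relative to t = 0, and the initial lesion density from the fragment
#' length (e.g. 2200 nt for the 2.2 kb GAL10 EcoRV/EcoRI fragment).
#'
#' @param timesMin Repair times (minutes), strictly increasing, first = 0.
#' @param bandPlus,bandMinus Band signals per time (same order), or
#'   alternatively \code{p0} directly.
#' @param fragmentLengthNt Restriction fragment length (nt).
#' @param p0 Optional intact-fraction series, bypassing the band pair.
#' @param tol Clamp tolerance passed to \code{\link{zeroClassFraction}}.
#' @return A \linkS4class{RepairCurve}; its \code{lesionsPerKb} slot holds
#'   mu(t) rescaled by the fragment length.
#' @examples
#' fragmentTimecourse(c(0, 30, 60, 120), p0 = c(0.33, 0.55, 0.74, 0.90),
#'                    fragmentLengthNt = 2200)
#' @export
fragmentTimecourse <- function(timesMin, bandPlus = NULL, bandMinus = NULL,
                               fragmentLengthNt, p0 = NULL, tol = 0.05) {
    stopifnot(is.numeric(timesMin), length(timesMin) >= 2L)
    if (any(diff(timesMin) <= 0) || timesMin[1L] != 0)
        stop("times must be strictly increasing and start at 0")
    if (is.null(p0)) {
        if (is.null(bandPlus) || is.null(bandMinus))
            stop("supply either p0 or both bandPlus and bandMinus")
        p0 <- zeroClassFraction(bandPlus, bandMinus, tol = tol)
    }
    if (length(p0) != length(timesMin))
        stop("one P0 per time point is required")
    mu <- zeroClassMu(as.numeric(p0))
    if (mu[1L] <= 0)
        stop("no initial damage: P0(0) = 1 gives mu0 = 0, cannot normalize")
    RepairCurve(timesMin = timesMin,
        percentRepair = 100 * (mu[1L] - mu) / mu[1L],
        lesionsPerKb = perKb(mu, fragmentLengthNt),
        initialPerKb = perKb(mu[1L], fragmentLengthNt))
}

#' Loading-normalized band ratio relative to a reference condition
#'
#' Generic western/northern quantification: the target band is divided by
#' its loading control and expressed relative to a reference ratio (e.g.
#' the wild-type untreated lane), which maps to 1.0.
#'
#' @param target,loading Band volumes; loading must be positive.
#' @param referenceRatio The target/loading ratio of the reference
#'   condition (> 0).
#' @return Dimensionless level relative to the reference.
#' @examples
#' normalizedBandRatio(4, 2, referenceRatio = 0.5)  # 4
#' @export
normalizedBandRatio <- function(target, loading, referenceRatio) {
    stopifnot(is.numeric(target), is.numeric(loading),
              is.numeric(referenceRatio))
    if (any(!is.finite(loading) | loading <= 0))
        stop("loading-control signal must be positive")
    if (any(!is.finite(referenceRatio) | referenceRatio <= 0))
        stop("reference ratio must be positive")
    if (any(!is.finite(target) | target < 0))
        stop("target signal must be non-negative")
    (target / loading) / referenceRatio
}

#' Mean and sample standard deviation across replicate experiments
#'
#' Arithmetic mean and the n-1 (sample) standard deviation, the summary
#' reported for independent experimental replicates.
#'
#' @param values Numeric vector of at least 2 replicate values.
#' @return Named list with \code{mean}, \code{sd} and \code{n}.
#' @examples
#' replicateSummary(c(0, 2))  # mean 1, sd sqrt(2)
#' @export
replicateSummary <- function(values) {
    stopifnot(is.numeric(values))
    if (length(values) < 2L)
        stop("at least 2 replicate values are required")
    if (anyNA(values) || any(!is.finite(values)))
        stop("replicate values must be finite")
    list(mean = mean(values), sd = sd(values), n = length(values))
}
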