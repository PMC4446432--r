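## Closed-form zero-class Poisson lesion statistics shared by all assays.

#' Zero-class Poisson lesion statistics
#'
#' Lesions on a restriction fragment are Poisson distributed, so the mean
#' lesion burden per fragment follows from the fraction of intact (uncut)
#' fragments alone: \code{mu = -ln(P0)}. \code{zeroClassMu} converts an
#' intact fraction to a burden; \code{expectedZeroFraction} is its inverse
#' \code{exp(-mu)}, used by the simulators and for round-trip checks;
#' \code{perKb} rescales a per-fragment burden to lesions per kilobase;
#' \code{percentRepair} expresses a later burden as percent of the initial
#' burden removed.
#'
#' @param p0 Fraction of intact (uncut) fragments, in (0, 1].
#' @param mu Mean lesions per fragment, >= 0.
#' @param fragmentLengthNt Fragment length in nucleotides, > 0.
#' @param mu0,muT Lesion burden at time zero (> 0) and at a later time
#'   (>= 0), in any common unit.
#' @return \code{zeroClassMu}: mean lesions per fragment (>= 0).
#'   \code{expectedZeroFraction}: intact fraction in (0, 1].
#'   \code{perKb}: lesions per 1000 nt. \code{percentRepair}: percentage of
#'   the initial burden removed; negative values (burden increased, i.e.
#'   measurement noise) are reported as-is, never clipped.
#' @examples
#' zeroClassMu(0.5)            # 0.6931
#' expectedZeroFraction(1)     # 0.3679
#' perKb(1.144, 1144)          # 1 lesion/kb
#' percentRepair(2, 0.5)       # 75
#' @name zero-class
NULL

#' @rdname zero-class
#' @export
zeroClassMu <- function(p0) {
    stopifnot(is.numeric(p0))
    bad <- !is.finite(p0) | p0 <= 0 | p0 > 1
    if (any(bad))
        stop(sprintf("intact fraction p0 must be in (0, 1]; got %s",
            paste(format(p0[bad]), collapse = ", ")))
    -log(p0)
}

#' @rdname zero-class
#' @export
expectedZeroFraction <- function(mu) {
    stopifnot(is.numeric(mu))
    bad <- !is.finite(mu) | mu < 0
    if (any(bad))
        stop(sprintf("lesion burden mu must be >= 0; got %s",
            paste(format(mu[bad]), collapse = ", ")))
    exp(-mu)
}

#' @rdname zero-class
#' @export
perKb <- function(mu, fragmentLengthNt) {
    stopifnot(is.numeric(mu), is.numeric(fragmentLengthNt))
    if (any(!is.finite(mu) | mu < 0))
        stop("lesion burden mu must be finite and >= 0")
    bad <- !is.finite(fragmentLengthNt) | fragmentLengthNt <= 0
    if (any(bad))
        stop(sprintf("fragment length must be positive; got %s",
            paste(format(fragmentLengthNt[bad]), collapse = ", ")))
    mu * 1000 / fragmentLengthNt
}

#' @rdname zero-class
#' @export
percentRepair <- function(mu0, muT) {
    stopifnot(is.numeric(mu0), is.numeric(muT))
    bad <- !is.finite(mu0) | mu0 <= 0
    if (any(bad))
        stop(sprintf("initial burden mu0 must be > 0; got %s",
            paste(format(mu0[bad]), collapse = ", ")))
    if (any(!is.finite(muT) | muT < 0))
        stop("later burden muT must be finite and >= 0")
    100 * (mu0 - muT) / mu0
}

#' Interpolated repair half-time of a fraction-remaining series
#'
#' Locates the first downward crossing of 0.5 in a fraction-remaining time
#' series and interpolates the crossing time log-linearly (linear in
#' log(fraction) versus time) between the bracketing samples. Under
#' first-order repair the fraction decays exponentially, and log-linear
#' interpolation recovers ln(2)/k exactly from any grid that brackets the
#' crossing. If no sample falls at or below 0.5 the half-time is censored.
#'
#' When the lower bracketing fraction is exactly 0 the log-linear formula
#' degenerates, and plain linear interpolation is used for that segment.
#'
#' @param times Strictly increasing sampling times (minutes), first = 0.
#' @param fractionRemaining Fractions in step with \code{times}; the first
#'   must be 1 (upstream normalization), all must be >= 0.
#' @return A \linkS4class{HalfTime}.
#' @examples
#' tHalf(interpolateHalfTime(c(0, 60), c(1, 0.5)))           # 60
#' k <- log(2) / 30
#' tHalf(interpolateHalfTime(c(0, 15, 30, 60), exp(-k * c(0, 15, 30, 60))))
#' isCensored(interpolateHalfTime(c(0, 30, 60), c(1, 0.9, 0.8)))
#' @export
interpolateHalfTime <- function(times, fractionRemaining) {
    stopifnot(is.numeric(times), is.numeric(fractionRemaining))
    if (length(times) != length(fractionRemaining))
        stop("times and fractionRemaining differ in length")
    if (length(times) < 2L)
        stop("at least 2 time points are required")
    if (anyNA(times) || any(!is.finite(times)) || any(diff(times) <= 0) ||
        times[1L] != 0)
        stop("times must be finite, strictly increasing and start at 0")
    f <- fractionRemaining
    if (anyNA(f) || any(!is.finite(f)) || any(f < 0))
        stop("fractions must be finite and >= 0")
    if (abs(f[1L] - 1) > 1e-6)
        stop(sprintf("fraction at t = 0 must be 1 (normalized); got %g",
                     f[1L]))
    idx <- which(f <= 0.5)[1L]
    if (is.na(idx))
        return(new("HalfTime", tHalf = NA_real_, censored = TRUE))
    t1 <- times[idx - 1L]; t2 <- times[idx]
    f1 <- f[idx - 1L];     f2 <- f[idx]
    th <- if (f2 > 0)
        t1 + (t2 - t1) * (log(f1) - log(0.5)) / (log(f1) - log(f2))
    else
        t1 + (t2 - t1) * (f1 - 0.5) / (f1 - f2)
    new("HalfTime", tHalf = th, censored = FALSE)
}
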