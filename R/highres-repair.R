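## High-resolution sequencing-gel analysis: Gaussian band deconvolution,
## fraction-remaining normalization, per-position half-times, 41-nt
## positional smoothing and nucleosome core/linker annotation.

#' Deconvolve overlapping sequencing-gel bands
#'
#' Fits a lane profile as a non-negative sum of Gaussians with fixed,
#' supplied band centers and a single shared width: a convex non-negative
#' least-squares problem with a deterministic solution (no initialization
#' sensitivity). Each fitted coefficient is the band's area in profile
#' units, since the design columns are unit-area Gaussian densities.
#'
#' @param profile A \linkS4class{LaneProfile}.
#' @param centers Band centers in migration units (the band registry).
#' @param sigma Shared Gaussian band SD (migration units, > 0).
#' @return Numeric vector of band areas, named by center, with attribute
#'   \code{"residualNorm"} (Euclidean norm of the fit residual).
#' @examples
#' m <- seq(0, 20, by = 0.05)
#' prof <- LaneProfile(m, 3 * dnorm(m, 8, 0.4) + 1 * dnorm(m, 12, 0.4))
#' deconvolveLane(prof, centers = c(8, 12), sigma = 0.4)
#' @export
deconvolveLane <- function(profile, centers, sigma) {
    stopifnot(is(profile, "LaneProfile"))
    if (!length(centers)) stop("the band center list is empty")
    if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
        stop("sigma must be a single positive number")
    sc <- sort(centers)
    gaps <- diff(sc)
    tooClose <- which(gaps < 0.1 * sigma)
    if (length(tooClose))
        stop(sprintf(
            "band centers closer than 0.1 sigma (ill-conditioned): %s",
            paste(sprintf("(%g, %g)", sc[tooClose], sc[tooClose + 1L]),
                  collapse = ", ")))
    m <- profile@migration
    D <- vapply(centers, function(cc) dnorm(m, cc, sigma),
                numeric(length(m)))
    y <- profile@intensity
    if (all(y == 0)) {
        out <- setNames(numeric(length(centers)), format(centers))
        attr(out, "residualNorm") <- 0
        return(out)
    }
    fit <- pracma::lsqnonneg(D, y)
    out <- setNames(as.numeric(fit$x), format(centers))
    attr(out, "residualNorm") <- sqrt(sum((as.numeric(D %*% fit$x) - y)^2))
    out
}

#' Deconvolve a sequencing-gel lane set into a band-kinetics table
#'
#' Applies \code{\link{deconvolveLane}} to one lane per time point against
#' a shared band registry (one center per damage site plus the full-length
#' band) and assembles the fitted band areas into a
#' \linkS4class{BandKineticsTable}.
#'
#' @param lanes List of \linkS4class{LaneProfile}, one per time, carrying
#'   \code{timeMin}.
#' @param centers Band centers in migration units, in the order
#'   \code{c(damage sites, full length)}.
#' @param sigma Shared Gaussian band SD.
#' @param positions Damage-site positions (nt) matching
#'   \code{centers[seq_along(positions)]}.
#' @param fragmentLengthNt Restriction fragment length (nt).
#' @return A \linkS4class{BandKineticsTable}.
#' @export
deconvolveKinetics <- function(lanes, centers, sigma, positions,
                               fragmentLengthNt = 1144) {
    stopifnot(is.list(lanes), length(centers) == length(positions) + 1L)
    times <- vapply(lanes, timeMin, numeric(1))
    if (anyNA(times) || anyDuplicated(times))
        stop("lanes must carry distinct timeMin values")
    o <- order(times)
    amps <- vapply(lanes[o], function(l)
        as.numeric(deconvolveLane(l, centers, sigma)),
        numeric(length(centers)))
    nP <- length(positions)
    BandKineticsTable(positions = positions, timesMin = times[o],
        intensities = amps[seq_len(nP), , drop = FALSE],
        fullLength = amps[nP + 1L, ],
        fragmentLengthNt = fragmentLengthNt)
}

#' Fraction of lesions remaining per position and time
#'
#' Converts a band-kinetics table to fractions remaining: each lane
#' (column) is first divided by its total signal (all damage bands plus the
#' full-length band) to correct for loading differences, then each damage
#' position is divided by its own loading-corrected t = 0 value. Fractions
#' at t = 0 are exactly 1. Positions with zero t = 0 signal cannot be
#' normalized; they are returned as \code{NA} rows with a warning rather
#' than aborting the analysis.
#'
#' @param table A \linkS4class{BandKineticsTable} whose times include 0.
#' @return Numeric matrix (damage positions x times) of fractions
#'   remaining, dimnames preserved.
#' @export
fractionRemaining <- function(table) {
    stopifnot(is(table, "BandKineticsTable"))
    tm <- timesMin(table)
    i0 <- which(tm == 0)
    if (length(i0) != 1L)
        stop("exactly one t = 0 column is required")
    dmg <- bandIntensities(table)
    totals <- colSums(dmg) + fullLengthIntensity(table)
    if (any(totals <= 0))
        stop("a lane has zero total signal; cannot loading-correct")
    norm <- sweep(dmg, 2L, totals, "/")
    base <- norm[, i0]
    unusable <- base <= 0
    if (any(unusable)) {
        warning(sprintf(
            "%d position(s) with zero t = 0 signal marked unusable: %s",
            sum(unusable),
            paste(positions(table)[unusable], collapse = ", ")))
        base[unusable] <- NA_real_
    }
    frac <- sweep(norm, 1L, base, "/")
    frac[, i0] <- ifelse(unusable, NA_real_, 1)
    frac
}

#' Per-position repair half-times from a fraction-remaining matrix
#'
#' Applies \code{\link{interpolateHalfTime}} to each position's
#' fraction-remaining series. Positions whose series never reaches 50
#' percent remaining are carried through as censored; unusable (all-NA)
#' positions are censored as well.
#'
#' @param fractions Matrix from \code{\link{fractionRemaining}} (positions
#'   x times).
#' @param timesMin Times (minutes) matching the columns, first = 0.
#' @param positions Nucleotide positions matching the rows.
#' @return A \linkS4class{THalfProfile} (not yet smoothed).
#' @export
tHalfProfile <- function(fractions, timesMin, positions) {
    fractions <- as.matrix(fractions)
    stopifnot(ncol(fractions) == length(timesMin),
              nrow(fractions) == length(positions))
    th <- rep(NA_real_, length(positions))
    cen <- rep(TRUE, length(positions))
    for (i in seq_along(positions)) {
        f <- fractions[i, ]
        if (anyNA(f)) next
        ht <- interpolateHalfTime(timesMin, f)
        if (!isCensored(ht)) {
            th[i] <- tHalf(ht)
            cen[i] <- FALSE
        }
    }
    THalfProfile(positions = positions, tHalf = th, censored = cen)
}

#' Positional moving-average smoothing of a half-time profile
#'
#' Centered moving average over nucleotide coordinates (not band index):
#' the smoothed value at a position is the mean of the non-censored
#' half-times of all observed damage sites within (window - 1)/2 nt on
#' either side, the position itself included. With the default 41-nt
#' window, that is the position plus 20 nt flanking each direction. Near
#' the fragment ends the window simply truncates to the available
#' positions; censored sites never contribute.
#'
#' @param profile A \linkS4class{THalfProfile}.
#' @param window Odd window width in nucleotides (default 41).
#' @return The profile with its \code{smoothed} slot filled (NA where no
#'   non-censored site falls in the window).
#' @export
smoothProfile <- function(profile, window = 41L) {
    stopifnot(is(profile, "THalfProfile"))
    if (window < 1 || window %% 2 == 0)
        stop(sprintf("window must be odd and >= 1; got %s", format(window)))
    half <- (window - 1) / 2
    pos <- profile@positions
    th <- profile@tHalf
    ok <- !profile@censored
    sm <- vapply(pos, function(p) {
        inWin <- ok & abs(pos - p) <= half
        if (any(inWin)) mean(th[inWin]) else NA_real_
    }, numeric(1))
    initialize(profile, smoothed = sm)
}

#' Annotate a half-time profile with nucleosome core/linker labels
#'
#' Labels each position \code{"core"} if it falls inside any supplied
#' nucleosome interval (1-based, inclusive, non-overlapping) and
#' \code{"linker"} otherwise.
#'
#' @param profile A \linkS4class{THalfProfile}.
#' @param coreIntervals An \code{IRanges}, or a 2-column matrix/data.frame
#'   of (start, end) pairs, 1-based inclusive.
#' @return The profile with its \code{nucleosomeLabel} slot filled.
#' @seealso \code{\link{nucleosomeSummary}}, \code{\link{bedToIntervals}}
#' @export
annotateNucleosomes <- function(profile, coreIntervals) {
    stopifnot(is(profile, "THalfProfile"))
    ir <- if (is(coreIntervals, "IRanges")) coreIntervals
          else {
              ci <- as.matrix(coreIntervals)
              if (nrow(ci) && any(ci[, 2L] < ci[, 1L]))
                  stop("interval end before start")
              IRanges::IRanges(start = as.integer(ci[, 1L]),
                               end = as.integer(ci[, 2L]))
          }
    if (length(ir) && !IRanges::isDisjoint(ir))
        stop("nucleosome intervals overlap; supply disjoint core intervals")
    lab <- rep("linker", length(profile@positions))
    if (length(ir)) {
        posR <- IRanges::IRanges(start = profile@positions, width = 1L)
        lab[IRanges::overlapsAny(posR, ir)] <- "core"
    }
    initialize(profile, nucleosomeLabel = lab)
}

#' Mean half-time by nucleosome label
#'
#' Group summary of an annotated profile: number of sites, number
#' censored, and the mean non-censored half-time for core and linker
#' positions.
#'
#' @param profile An annotated \linkS4class{THalfProfile}.
#' @return data.frame with columns label, n, n_censored, mean_t_half_min.
#' @export
nucleosomeSummary <- function(profile) {
    stopifnot(is(profile, "THalfProfile"))
    lab <- profile@nucleosomeLabel
    if (!length(lab))
        stop("profile is not annotated; run annotateNucleosomes() first")
    do.call(rbind, lapply(split(seq_along(lab), lab), function(i) {
        data.frame(label = lab[i[1L]], n = length(i),
            n_censored = sum(profile@censored[i]),
            mean_t_half_min = mean(profile@tHalf[i], na.rm = TRUE))
    })) -> out
    rownames(out) <- NULL
    out
}

#' Convert 0-based half-open (BED-like) intervals to 1-based inclusive
#'
#' Internal coordinates are 1-based inclusive; BED-like inputs declare the
#' 0-based half-open convention and are converted here.
#'
#' @param start0 0-based starts.
#' @param end0 Half-open ends (exclusive).
#' @return An \code{IRanges} in 1-based inclusive coordinates.
#' @examples
#' bedToIntervals(0, 147)  # becomes [1, 147]
#' @export
bedToIntervals <- function(start0, end0) {
    stopifnot(is.numeric(start0), is.numeric(end0),
              length(start0) == length(end0))
    if (any(end0 <= start0)) stop("BED intervals must have end > start")
    IRanges::IRanges(start = as.integer(start0) + 1L,
                     end = as.integer(end0))
}
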