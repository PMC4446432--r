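#' @include AllGenerics.R
#' @importFrom stats approx dnorm median rbinom rexp rpois runif sd setNames cor rnorm
#' @importFrom utils read.delim write.table head tail
NULL

.checkNumeric <- function(x, what) {
    if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
        return(sprintf("'%s' must be finite numeric without NA", what))
    NULL
}

## ---------------------------------------------------------------------------
## LaneProfile: one gel lane as ordered (migration, intensity) samples
## ---------------------------------------------------------------------------

#' LaneProfile: a densitometric gel-lane profile
#'
#' One gel lane quantified by densitometry, as ordered samples of stain
#' intensity along the migration coordinate (well at small values, gel bottom
#' at large values). Intensity is assumed mass-proportional for
#' double-strand stains (SYBR-Gold-like) and count-proportional for
#' end-labeled sequencing gels; the analysis functions state which they use.
#'
#' @slot migration Numeric, strictly increasing migration coordinates
#'   (arbitrary gel units).
#' @slot intensity Numeric signal per sample; raw profiles may dip below
#'   zero around an empty baseline (detector noise), background
#'   subtraction clips at zero.
#' @slot label Character scalar lane identifier.
#' @slot enzymeTreated Logical scalar: lesion-cleaving enzyme cocktail
#'   (AAG/APE1) applied (\code{TRUE}) or mock (\code{FALSE}).
#' @slot timeMin Numeric scalar repair time in minutes.
#'
#' @param migration,intensity,label,enzymeTreated,timeMin See slots.
#' @return \code{LaneProfile()} returns a \code{LaneProfile} object.
#' @examples
#' lp <- LaneProfile(migration = 1:20, intensity = rep(1, 20), label = "L1")
#' migration(lp)[1:3]
#' @aliases migration intensity laneLabel enzymeTreated timeMin
#' @export LaneProfile
#' @exportClass LaneProfile
setClass("LaneProfile",
    representation(migration = "numeric", intensity = "numeric",
        label = "character", enzymeTreated = "logical", timeMin = "numeric"),
    validity = function(object) {
        msg <- c(.checkNumeric(object@migration, "migration"),
                 .checkNumeric(object@intensity, "intensity"))
        if (length(object@migration) != length(object@intensity))
            msg <- c(msg, "migration and intensity differ in length")
        if (length(object@migration) < 10L)
            msg <- c(msg, "a lane profile needs at least 10 samples")
        if (is.null(msg) || length(msg) == 0L) {
            if (any(diff(object@migration) <= 0))
                msg <- c(msg, "migration must be strictly increasing")
            ## raw profiles may dip below zero around an empty baseline
            ## (detector noise); background subtraction clips at zero
        }
        if (length(msg)) msg else TRUE
    })

LaneProfile <- function(migration, intensity, label = "lane",
                        enzymeTreated = NA, timeMin = NA_real_) {
    new("LaneProfile", migration = as.numeric(migration),
        intensity = as.numeric(intensity), label = as.character(label),
        enzymeTreated = as.logical(enzymeTreated),
        timeMin = as.numeric(timeMin))
}

#' @rdname LaneProfile-class
#' @export
setMethod("migration", "LaneProfile", function(x) x@migration)
#' @rdname LaneProfile-class
#' @export
setMethod("intensity", "LaneProfile", function(x) x@intensity)
#' @rdname LaneProfile-class
#' @export
setMethod("laneLabel", "LaneProfile", function(x) x@label)
#' @rdname LaneProfile-class
#' @export
setMethod("enzymeTreated", "LaneProfile", function(x) x@enzymeTreated)
#' @rdname LaneProfile-class
#' @export
setMethod("timeMin", "LaneProfile", function(x) x@timeMin)

setMethod("show", "LaneProfile", function(object) {
    cat(sprintf("LaneProfile '%s': %d samples, migration [%.3g, %.3g]\n",
        object@label, length(object@migration),
        min(object@migration), max(object@migration)))
    cat(sprintf("  enzymeTreated: %s, time: %s min, total signal: %.4g\n",
        object@enzymeTreated, format(object@timeMin),
        sum(object@intensity)))
})

## ---------------------------------------------------------------------------
## SizeLadder and MigrationMap
## ---------------------------------------------------------------------------

#' SizeLadder: migration/length calibration pairs
#'
#' Calibration knots pairing a migration coordinate with a known fragment
#' length. Longer fragments migrate less, so migration must be strictly
#' increasing while length is strictly decreasing.
#'
#' @slot migration Numeric, strictly increasing migration coordinates.
#' @slot lengthNt Numeric, strictly decreasing fragment lengths (nt).
#' @param migration,lengthNt See slots.
#' @return A \code{SizeLadder}.
#' @examples
#' SizeLadder(migration = c(10, 20, 30), lengthNt = c(10000, 1000, 100))
#' @export SizeLadder
#' @exportClass SizeLadder
setClass("SizeLadder",
    representation(migration = "numeric", lengthNt = "numeric"),
    validity = function(object) {
        msg <- c(.checkNumeric(object@migration, "migration"),
                 .checkNumeric(object@lengthNt, "lengthNt"))
        if (length(object@migration) != length(object@lengthNt))
            msg <- c(msg, "migration and lengthNt differ in length")
        if (length(object@migration) < 2L)
            msg <- c(msg, "a ladder needs at least 2 calibration pairs")
        if (length(msg) == 0L) {
            if (any(object@lengthNt <= 0))
                msg <- c(msg, "fragment lengths must be positive")
            bad <- which(diff(object@migration) <= 0)
            if (length(bad))
                msg <- c(msg, sprintf(
                    "ladder migration not strictly increasing at pair(s) %s",
                    paste(bad + 1L, collapse = ", ")))
            bad <- which(diff(object@lengthNt) >= 0)
            if (length(bad))
                msg <- c(msg, sprintf(
                    "ladder lengths not strictly decreasing at pair(s) %s",
                    paste(bad + 1L, collapse = ", ")))
        }
        if (length(msg)) msg else TRUE
    })

SizeLadder <- function(migration, lengthNt) {
    new("SizeLadder", migration = as.numeric(migration),
        lengthNt = as.numeric(lengthNt))
}

setMethod("show", "SizeLadder", function(object) {
    cat(sprintf("SizeLadder: %d knots, %g-%g nt\n",
        length(object@migration), max(object@lengthNt),
        min(object@lengthNt)))
})

#' MigrationMap: calibrated migration-to-length function
#'
#' A monotone map from migration coordinate to fragment length built by
#' \code{\link{fitLadder}}: piecewise-linear in log10(length) versus
#' migration, with linear extrapolation (flagged) beyond the outermost
#' knots. Reproduces the ladder knots exactly.
#'
#' @slot migrationKnots Numeric, increasing knot migrations.
#' @slot log10LengthKnots Numeric, decreasing log10 length at the knots.
#' @aliases migrationToLength
#' @examples
#' mm <- fitLadder(SizeLadder(c(10, 20), c(10000, 1000)))
#' migrationToLength(mm, 15)  # geometric mean, 3162.28
#' @export
#' @exportClass MigrationMap
setClass("MigrationMap",
    representation(migrationKnots = "numeric", log10LengthKnots = "numeric"),
    validity = function(object) {
        if (any(diff(object@migrationKnots) <= 0))
            return("migration knots must be strictly increasing")
        if (any(diff(object@log10LengthKnots) >= 0))
            return("log10 length knots must be strictly decreasing")
        TRUE
    })

setMethod("show", "MigrationMap", function(object) {
    cat(sprintf(
        "MigrationMap: %d knots, valid migration range [%.4g, %.4g]\n",
        length(object@migrationKnots), min(object@migrationKnots),
        max(object@migrationKnots)))
})

## ---------------------------------------------------------------------------
## EnsembleAverage
## ---------------------------------------------------------------------------

#' EnsembleAverage: number-average fragment length of a lane
#'
#' The ensemble (number-)average fragment length Ln of a lane: total DNA
#' mass over total molecule count, computed by
#' \code{\link{ensembleAverageLength}} as the mass-weighted harmonic mean of
#' fragment length.
#'
#' @slot lengthNt Positive numeric scalar, Ln in nucleotides.
#' @slot label Character lane label.
#' @slot censored Logical: \code{TRUE} when the lane's molecule-count
#'   signal was indistinguishable from zero and Ln was censored at the
#'   upper length bound (an intact, essentially unfragmented lane).
#' @export
#' @exportClass EnsembleAverage
setClass("EnsembleAverage",
    representation(lengthNt = "numeric", label = "character",
        censored = "logical"),
    prototype(censored = FALSE),
    validity = function(object) {
        if (length(object@lengthNt) != 1L || !is.finite(object@lengthNt) ||
            object@lengthNt <= 0)
            return("lengthNt must be a single positive finite number")
        TRUE
    })

setMethod("show", "EnsembleAverage", function(object) {
    cat(sprintf("EnsembleAverage '%s': Ln = %.6g nt%s\n",
        object@label, object@lengthNt,
        if (isTRUE(object@censored)) " (censored at bound)" else ""))
})

#' @rdname EnsembleAverage-class
#' @param x An \code{EnsembleAverage}.
#' @export
ensembleLengthNt <- function(x) {
    stopifnot(is(x, "EnsembleAverage"))
    x@lengthNt
}

## ---------------------------------------------------------------------------
## RepairCurve
## ---------------------------------------------------------------------------

#' RepairCurve: a percent-repair time series
#'
#' Time series of percent lesions removed relative to the t = 0 burden,
#' together with the per-time lesion densities and the initial lesions/kb.
#' Negative percent repair (measurement noise) is preserved, not clipped.
#'
#' @slot timesMin Numeric, strictly increasing sampling times (minutes),
#'   starting at 0.
#' @slot percentRepair Numeric, percent of initial lesions removed at each
#'   time; 0 at t = 0 by construction.
#' @slot lesionsPerKb Numeric, lesion density (per kb) at each time (may be
#'   all \code{NA} when only a dimensionless burden was measured).
#' @slot initialPerKb Numeric scalar, lesions/kb at t = 0.
#'
#' @param timesMin,percentRepair,lesionsPerKb,initialPerKb See slots.
#' @aliases timesMin repairPercent lesionsPerKb initialPerKb
#' @examples
#' rc <- RepairCurve(timesMin = c(0, 60, 120), percentRepair = c(0, 40, 70),
#'                   initialPerKb = 0.9)
#' repairPercent(rc)
#' @export RepairCurve
#' @exportClass RepairCurve
setClass("RepairCurve",
    representation(timesMin = "numeric", percentRepair = "numeric",
        lesionsPerKb = "numeric", initialPerKb = "numeric"),
    validity = function(object) {
        msg <- c(.checkNumeric(object@timesMin, "timesMin"),
                 .checkNumeric(object@percentRepair, "percentRepair"))
        if (length(msg) == 0L) {
            if (length(object@timesMin) != length(object@percentRepair))
                msg <- c(msg, "timesMin and percentRepair differ in length")
            else {
                if (any(diff(object@timesMin) <= 0))
                    msg <- c(msg, "times must be strictly increasing")
                if (object@timesMin[1L] != 0)
                    msg <- c(msg, "the first time point must be 0")
                if (abs(object@percentRepair[1L]) > 1e-9)
                    msg <- c(msg, "percent repair at t = 0 must be 0")
            }
            if (length(object@lesionsPerKb) &&
                length(object@lesionsPerKb) != length(object@timesMin))
                msg <- c(msg, "lesionsPerKb length mismatch")
        }
        if (length(msg)) msg else TRUE
    })

RepairCurve <- function(timesMin, percentRepair,
                        lesionsPerKb = numeric(0),
                        initialPerKb = NA_real_) {
    new("RepairCurve", timesMin = as.numeric(timesMin),
        percentRepair = as.numeric(percentRepair),
        lesionsPerKb = as.numeric(lesionsPerKb),
        initialPerKb = as.numeric(initialPerKb))
}

#' @rdname RepairCurve-class
#' @param x A \code{RepairCurve}.
#' @export
setMethod("timesMin", "RepairCurve", function(x) x@timesMin)
#' @rdname RepairCurve-class
#' @export
setMethod("repairPercent", "RepairCurve", function(x) x@percentRepair)
#' @rdname RepairCurve-class
#' @export
setMethod("lesionsPerKb", "RepairCurve", function(x) x@lesionsPerKb)
#' @rdname RepairCurve-class
#' @export
setMethod("initialPerKb", "RepairCurve", function(x) x@initialPerKb)

setMethod("show", "RepairCurve", function(object) {
    cat(sprintf("RepairCurve: %d time points, initial %.4g lesions/kb\n",
        length(object@timesMin), object@initialPerKb))
    df <- data.frame(time_min = object@timesMin,
        percent_repair = round(object@percentRepair, 2))
    if (length(object@lesionsPerKb))
        df$lesions_per_kb <- signif(object@lesionsPerKb, 4)
    print(df, row.names = FALSE)
})

#' @rdname RepairCurve-class
#' @export
as.data.frame.RepairCurve <- function(x, ...) {
    df <- data.frame(time_min = x@timesMin, percent_repair = x@percentRepair)
    if (length(x@lesionsPerKb)) df$lesions_per_kb <- x@lesionsPerKb
    df
}

## ---------------------------------------------------------------------------
## HalfTime
## ---------------------------------------------------------------------------

#' HalfTime: repair half-time or censoring marker
#'
#' The time at which half the initial lesions remain, or a censoring marker
#' when the series never reaches 50 percent remaining. Exactly one of the
#' two states holds.
#'
#' @slot tHalf Numeric scalar in minutes (\code{NA} when censored).
#' @slot censored Logical scalar.
#' @export
#' @exportClass HalfTime
setClass("HalfTime",
    representation(tHalf = "numeric", censored = "logical"),
    validity = function(object) {
        if (length(object@tHalf) != 1L || length(object@censored) != 1L)
            return("tHalf and censored must be scalars")
        if (object@censored && !is.na(object@tHalf))
            return("a censored HalfTime carries no finite tHalf")
        if (!object@censored &&
            (is.na(object@tHalf) || object@tHalf <= 0))
            return("a non-censored HalfTime must be finite and positive")
        TRUE
    })

setMethod("show", "HalfTime", function(object) {
    if (object@censored) cat("HalfTime: censored (never reached 50%)\n")
    else cat(sprintf("HalfTime: %.6g min\n", object@tHalf))
})

#' @rdname HalfTime-class
#' @param x A \code{HalfTime}.
#' @export
setMethod("tHalf", "HalfTime", function(x) x@tHalf)
#' @rdname HalfTime-class
#' @export
setMethod("isCensored", "HalfTime", function(x) x@censored)

## ---------------------------------------------------------------------------
## BandKineticsTable (SummarizedExperiment subclass)
## ---------------------------------------------------------------------------

#' BandKineticsTable: sequencing-gel band intensities by position and time
#'
#' A position-by-time matrix of deconvolved sequencing-gel band intensities
#' for one end-labeled restriction fragment, stored as a
#' \linkS4class{SummarizedExperiment}: rows are damage-site nucleotide
#' positions (1-based, non-transcribed strand, increasing away from the
#' labeled end) plus one full-length row; columns are repair time points.
#'
#' @slot . Inherits all slots from \code{SummarizedExperiment}; rowData
#'   carries \code{position_nt} and \code{role} ("damage" or
#'   "full_length"), colData carries \code{time_min}.
#'
#' @param positions Integer-ish vector of damage-site positions (nt).
#' @param timesMin Numeric vector of repair times (minutes).
#' @param intensities Numeric matrix, positions x times, all >= 0.
#' @param fullLength Numeric vector of full-length band intensity per time.
#' @param fragmentLengthNt Length of the restriction fragment (nt).
#' @return \code{BandKineticsTable()} returns a \code{BandKineticsTable}.
#' @aliases positions,BandKineticsTable-method
#'   timesMin,BandKineticsTable-method bandIntensities fullLengthIntensity
#'   fragmentLength
#' @examples
#' bkt <- BandKineticsTable(positions = c(100L, 300L),
#'     timesMin = c(0, 60), intensities = rbind(c(4, 2), c(6, 3)),
#'     fullLength = c(90, 95), fragmentLengthNt = 1144)
#' positions(bkt)
#' @export BandKineticsTable
#' @exportClass BandKineticsTable
setClass("BandKineticsTable", contains = "SummarizedExperiment",
    validity = function(object) {
        rd <- SummarizedExperiment::rowData(object)
        cd <- SummarizedExperiment::colData(object)
        if (!all(c("position_nt", "role") %in% colnames(rd)))
            return("rowData must carry position_nt and role")
        if (!"time_min" %in% colnames(cd))
            return("colData must carry time_min")
        if (sum(rd$role == "full_length") != 1L)
            return("exactly one full_length row is required")
        a <- SummarizedExperiment::assay(object, "intensity")
        if (any(a < 0)) return("band intensities must be non-negative")
        pos <- rd$position_nt[rd$role == "damage"]
        if (anyNA(pos) || any(pos < 1))
            return("damage positions must be >= 1")
        if (is.unsorted(pos, strictly = TRUE))
            return("damage positions must be strictly increasing")
        TRUE
    })

BandKineticsTable <- function(positions, timesMin, intensities, fullLength,
                              fragmentLengthNt = NA_real_) {
    intensities <- as.matrix(intensities)
    stopifnot(length(positions) == nrow(intensities),
              length(timesMin) == ncol(intensities),
              length(fullLength) == length(timesMin))
    o <- order(positions)
    positions <- as.integer(positions[o])
    intensities <- intensities[o, , drop = FALSE]
    assay <- rbind(intensities, matrix(fullLength, nrow = 1L))
    rownames(assay) <- c(sprintf("pos_%d", positions), "full_length")
    colnames(assay) <- sprintf("t_%g", timesMin)
    rd <- S4Vectors::DataFrame(
        position_nt = c(positions, NA_integer_),
        role = c(rep("damage", length(positions)), "full_length"))
    cd <- S4Vectors::DataFrame(time_min = as.numeric(timesMin))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = assay), rowData = rd, colData = cd,
        metadata = list(fragment_length_nt = as.numeric(fragmentLengthNt)))
    new("BandKineticsTable", se)
}

#' @rdname BandKineticsTable-class
#' @param x A \code{BandKineticsTable}.
#' @export
setMethod("positions", "BandKineticsTable", function(x) {
    rd <- SummarizedExperiment::rowData(x)
    rd$position_nt[rd$role == "damage"]
})

#' @rdname BandKineticsTable-class
#' @export
setMethod("timesMin", "BandKineticsTable", function(x)
    SummarizedExperiment::colData(x)$time_min)

#' @rdname BandKineticsTable-class
#' @export
bandIntensities <- function(x) {
    stopifnot(is(x, "BandKineticsTable"))
    rd <- SummarizedExperiment::rowData(x)
    SummarizedExperiment::assay(x, "intensity")[rd$role == "damage", ,
        drop = FALSE]
}

#' @rdname BandKineticsTable-class
#' @export
fullLengthIntensity <- function(x) {
    stopifnot(is(x, "BandKineticsTable"))
    rd <- SummarizedExperiment::rowData(x)
    SummarizedExperiment::assay(x, "intensity")[rd$role == "full_length", ]
}

#' @rdname BandKineticsTable-class
#' @export
fragmentLength <- function(x) {
    stopifnot(is(x, "BandKineticsTable"))
    S4Vectors::metadata(x)$fragment_length_nt
}

## ---------------------------------------------------------------------------
## THalfProfile
## ---------------------------------------------------------------------------

#' THalfProfile: per-nucleotide repair half-times along a fragment
#'
#' Per-position repair half-times on an end-labeled restriction fragment,
#' with censoring markers, an optional positional moving-average smooth,
#' and optional nucleosome core/linker labels.
#'
#' @slot positions Integer nucleotide positions (1-based, strictly
#'   increasing).
#' @slot tHalf Numeric half-times in minutes (\code{NA} where censored).
#' @slot censored Logical, per position.
#' @slot smoothed Numeric, positional moving-average of the non-censored
#'   half-times (NA until \code{\link{smoothProfile}} is applied).
#' @slot nucleosomeLabel Character, "core"/"linker" (empty until
#'   \code{\link{annotateNucleosomes}} is applied).
#'
#' @param positions,tHalf,censored See slots.
#' @aliases positions tHalf isCensored smoothedTHalf nucleosomeLabel
#' @export THalfProfile
#' @exportClass THalfProfile
setClass("THalfProfile",
    representation(positions = "integer", tHalf = "numeric",
        censored = "logical", smoothed = "numeric",
        nucleosomeLabel = "character"),
    validity = function(object) {
        n <- length(object@positions)
        if (length(object@tHalf) != n || length(object@censored) != n)
            return("positions, tHalf and censored must align")
        if (is.unsorted(object@positions, strictly = TRUE))
            return("positions must be strictly increasing")
        if (any(object@censored & !is.na(object@tHalf)))
            return("censored positions must carry NA tHalf")
        if (any(!object@censored &
                (is.na(object@tHalf) | object@tHalf <= 0)))
            return("non-censored positions need positive finite tHalf")
        if (length(object@smoothed) && length(object@smoothed) != n)
            return("smoothed length mismatch")
        if (length(object@nucleosomeLabel) &&
            length(object@nucleosomeLabel) != n)
            return("nucleosomeLabel length mismatch")
        TRUE
    })

THalfProfile <- function(positions, tHalf, censored = is.na(tHalf)) {
    tHalf <- as.numeric(tHalf)
    tHalf[censored] <- NA_real_
    new("THalfProfile", positions = as.integer(positions), tHalf = tHalf,
        censored = as.logical(censored), smoothed = numeric(0),
        nucleosomeLabel = character(0))
}

#' @rdname THalfProfile-class
#' @param x A \code{THalfProfile}.
#' @export
setMethod("positions", "THalfProfile", function(x) x@positions)
#' @rdname THalfProfile-class
#' @export
setMethod("tHalf", "THalfProfile", function(x) x@tHalf)
#' @rdname THalfProfile-class
#' @export
setMethod("isCensored", "THalfProfile", function(x) x@censored)
#' @rdname THalfProfile-class
#' @export
setMethod("smoothedTHalf", "THalfProfile", function(x) {
    if (length(x@smoothed)) x@smoothed else rep(NA_real_, length(x@positions))
})
#' @rdname THalfProfile-class
#' @export
setMethod("nucleosomeLabel", "THalfProfile", function(x) {
    if (length(x@nucleosomeLabel)) x@nucleosomeLabel
    else rep(NA_character_, length(x@positions))
})

setMethod("show", "THalfProfile", function(object) {
    cat(sprintf(
        "THalfProfile: %d positions (%d censored)%s%s\n",
        length(object@positions), sum(object@censored),
        if (length(object@smoothed)) ", smoothed" else "",
        if (length(object@nucleosomeLabel)) ", nucleosome-annotated" else ""))
})

#' @rdname THalfProfile-class
#' @param ... Unused.
#' @export
as.data.frame.THalfProfile <- function(x, ...) {
    data.frame(position_nt = x@positions, t_half_min = x@tHalf,
        censored = x@censored, smoothed_t_half_min = smoothedTHalf(x),
        nucleosome_label = nucleosomeLabel(x))
}

## ---------------------------------------------------------------------------
## Simulator models
## ---------------------------------------------------------------------------

#' GelModel: electrophoretic migration and band-spread model
#'
#' Migration law m(L) = a - b log10(L) with Gaussian band spread of fixed
#' width and optional additive Gaussian noise, used by the forward
#' simulators to render lane profiles.
#'
#' @slot interceptA,slopeB Migration-law coefficients (both > 0).
#' @slot bandSigma Gaussian band standard deviation (migration units).
#' @slot noiseSd Additive Gaussian noise SD (intensity units; 0 = none).
#' @slot lengthRange Fragment lengths (nt) the rendered lane covers; an
#'   ideal lane records every fragment, so the default range is wide.
#' @slot gridStep Migration sampling step of the rendered profile.
#'
#' @param interceptA,slopeB,bandSigma,noiseSd,lengthRange,gridStep See slots.
#' @examples
#' gm <- GelModel(bandSigma = 0.5)
#' migrationOf(gm, c(1000, 10000))
#' @export GelModel
#' @exportClass GelModel
setClass("GelModel",
    representation(interceptA = "numeric", slopeB = "numeric",
        bandSigma = "numeric", noiseSd = "numeric",
        lengthRange = "numeric", gridStep = "numeric"),
    validity = function(object) {
        if (object@slopeB <= 0 || object@bandSigma <= 0)
            return("slopeB and bandSigma must be positive")
        if (object@noiseSd < 0) return("noiseSd must be >= 0")
        if (length(object@lengthRange) != 2L ||
            object@lengthRange[1L] <= 0 ||
            diff(object@lengthRange) <= 0)
            return("lengthRange must be an increasing positive pair")
        if (object@gridStep <= 0) return("gridStep must be positive")
        TRUE
    })

GelModel <- function(interceptA = 100, slopeB = 30, bandSigma = 0.5,
                     noiseSd = 0, lengthRange = c(1, 2e5),
                     gridStep = bandSigma / 5) {
    new("GelModel", interceptA = as.numeric(interceptA),
        slopeB = as.numeric(slopeB), bandSigma = as.numeric(bandSigma),
        noiseSd = as.numeric(noiseSd),
        lengthRange = as.numeric(lengthRange),
        gridStep = as.numeric(gridStep))
}

setMethod("show", "GelModel", function(object) {
    cat(sprintf(
        "GelModel: m(L) = %g - %g log10(L), sigma %g, noise sd %g\n",
        object@interceptA, object@slopeB, object@bandSigma, object@noiseSd))
})

#' @rdname GelModel-class
#' @param gel A \code{GelModel}.
#' @param lengthNt Fragment lengths (nt).
#' @return \code{migrationOf()} returns the migration coordinate of each
#'   length under the gel's law.
#' @export
migrationOf <- function(gel, lengthNt) {
    stopifnot(is(gel, "GelModel"))
    gel@interceptA - gel@slopeB * log10(lengthNt)
}

#' LesionField: lesion positions on one DNA molecule
#'
#' Sorted, unique 1-based lesion positions on a molecule of known length,
#' as produced by \code{\link{simulateLesions}} (Poisson lesion count,
#' uniform placement without replacement).
#'
#' @slot lengthNt Molecule length (nt).
#' @slot positions Sorted unique integer lesion positions in [1, lengthNt].
#' @slot ratePerKb Generating lesion rate (per kb).
#' @export
#' @exportClass LesionField
setClass("LesionField",
    representation(lengthNt = "numeric", positions = "integer",
        ratePerKb = "numeric"),
    validity = function(object) {
        if (object@lengthNt <= 0) return("lengthNt must be positive")
        p <- object@positions
        if (length(p)) {
            if (anyDuplicated(p)) return("lesion positions must be unique")
            if (is.unsorted(p)) return("lesion positions must be sorted")
            if (min(p) < 1L || max(p) > object@lengthNt)
                return("lesion positions must lie in [1, lengthNt]")
        }
        TRUE
    })

setMethod("show", "LesionField", function(object) {
    cat(sprintf("LesionField: %d lesions on %g nt (rate %g/kb)\n",
        length(object@positions), object@lengthNt, object@ratePerKb))
})

#' RepairModel: per-site first-order repair rates
#'
#' Per-site repair rate constants, optionally attenuated by a nucleosome
#' occupancy profile: k_site = kBase * (1 - alpha * occupancy_site), so
#' alpha = 1 with occupancy 1 shuts repair off entirely at that site.
#'
#' @slot sitePositions Integer site positions (nt).
#' @slot rateConstants Per-site first-order rates k (1/min), all >= 0.
#'
#' @param sitePositions Site positions (nt).
#' @param rateConstants Per-site rates; recycled if scalar. Either this or
#'   \code{kBase} must be given.
#' @param kBase Scalar base rate used with the occupancy model.
#' @param occupancy Per-site occupancy in [0, 1] (default 0).
#' @param alpha Occupancy attenuation in [0, 1] (default 0).
#' @examples
#' RepairModel(c(50L, 500L), kBase = log(2) / 30,
#'             occupancy = c(0, 1), alpha = 0.5)
#' @export RepairModel
#' @exportClass RepairModel
setClass("RepairModel",
    representation(sitePositions = "integer", rateConstants = "numeric"),
    validity = function(object) {
        if (length(object@sitePositions) != length(object@rateConstants))
            return("sitePositions and rateConstants must align")
        if (any(object@rateConstants < 0))
            return("rate constants must be >= 0")
        TRUE
    })

RepairModel <- function(sitePositions, rateConstants = NULL, kBase = NULL,
                        occupancy = 0, alpha = 0) {
    sitePositions <- as.integer(sitePositions)
    if (is.null(rateConstants)) {
        stopifnot(!is.null(kBase), alpha >= 0, alpha <= 1,
                  all(occupancy >= 0), all(occupancy <= 1))
        occupancy <- rep_len(occupancy, length(sitePositions))
        rateConstants <- kBase * (1 - alpha * occupancy)
    }
    new("RepairModel", sitePositions = sitePositions,
        rateConstants = rep_len(as.numeric(rateConstants),
                                length(sitePositions)))
}

setMethod("show", "RepairModel", function(object) {
    cat(sprintf("RepairModel: %d sites, k in [%.4g, %.4g] /min\n",
        length(object@sitePositions),
        if (length(object@rateConstants)) min(object@rateConstants) else NA,
        if (length(object@rateConstants)) max(object@rateConstants) else NA))
})

#' @rdname RepairModel-class
#' @param x A \code{RepairModel}.
#' @export
rateConstants <- function(x) {
    stopifnot(is(x, "RepairModel"))
    setNames(x@rateConstants, x@sitePositions)
}
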