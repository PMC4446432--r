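## Readers and writers for the plain-text table dialects the assays use.

#' Read a lane profile from a two-column table
#'
#' Tab- or comma-separated file with columns \code{migration} and
#' \code{intensity} (one lane per file).
#'
#' @param file Path.
#' @param label,enzymeTreated,timeMin Lane metadata (not stored in the
#'   file).
#' @param sep Field separator (default tab).
#' @return A \linkS4class{LaneProfile}.
#' @export
readLaneProfile <- function(file, label = basename(file),
                            enzymeTreated = NA, timeMin = NA_real_,
                            sep = "\t") {
    df <- read.delim(file, sep = sep)
    need <- c("migration", "intensity")
    if (!all(need %in% names(df)))
        stop(sprintf("'%s' must have columns: %s", file,
                     paste(need, collapse = ", ")))
    LaneProfile(df$migration, df$intensity, label = label,
                enzymeTreated = enzymeTreated, timeMin = timeMin)
}

#' Write a lane profile to a two-column TSV
#' @param profile A \linkS4class{LaneProfile}.
#' @param file Path.
#' @export
writeLaneProfile <- function(profile, file) {
    stopifnot(is(profile, "LaneProfile"))
    write.table(data.frame(migration = migration(profile),
                           intensity = intensity(profile)),
        file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Read a size ladder from a two-column TSV
#'
#' Columns \code{migration} and \code{length_nt}; rows in any order.
#'
#' @param file Path.
#' @param sep Field separator.
#' @return A \linkS4class{SizeLadder}.
#' @export
readSizeLadder <- function(file, sep = "\t") {
    df <- read.delim(file, sep = sep)
    need <- c("migration", "length_nt")
    if (!all(need %in% names(df)))
        stop(sprintf("'%s' must have columns: %s", file,
                     paste(need, collapse = ", ")))
    df <- df[order(df$migration), ]
    SizeLadder(df$migration, df$length_nt)
}

#' Read a band-measurement table
#'
#' Long-format TSV with columns \code{lane}, \code{time_min}, \code{role}
#' (one of plus, minus, target, loading) and \code{signal}, covering both
#' Southern zero-class pairs and western/northern target-loading pairs.
#'
#' @param file Path.
#' @param sep Field separator.
#' @return data.frame.
#' @export
readBandTable <- function(file, sep = "\t") {
    df <- read.delim(file, sep = sep)
    need <- c("lane", "time_min", "role", "signal")
    if (!all(need %in% names(df)))
        stop(sprintf("'%s' must have columns: %s", file,
                     paste(need, collapse = ", ")))
    ok <- c("plus", "minus", "target", "loading")
    if (!all(df$role %in% ok))
        stop(sprintf("unknown role(s): %s",
            paste(unique(setdiff(df$role, ok)), collapse = ", ")))
    if (any(df$signal < 0)) stop("band signals must be non-negative")
    df
}

#' Read a plating-record table
#'
#' TSV with columns \code{strain}, \code{treated} (logical or 0/1),
#' \code{replicate}, \code{selective_colonies},
#' \code{cells_plated_selective}, \code{titer_colonies},
#' \code{titer_dilution}.
#'
#' @param file Path.
#' @param sep Field separator.
#' @return data.frame ready for \code{\link{mutagenesisTable}}.
#' @export
readPlatingTable <- function(file, sep = "\t") {
    df <- read.delim(file, sep = sep)
    need <- c("strain", "treated", "replicate", "selective_colonies",
              "cells_plated_selective", "titer_colonies", "titer_dilution")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop(sprintf("'%s' lacks column(s): %s", file,
                     paste(miss, collapse = ", ")))
    df$treated <- as.logical(df$treated)
    df
}

#' Read a sequencing-gel band registry
#'
#' TSV with columns \code{position_nt} (damage-site nucleotide position)
#' and \code{migration_center} (band center in migration units).
#'
#' @param file Path.
#' @param sep Field separator.
#' @return data.frame sorted by position.
#' @export
readBandRegistry <- function(file, sep = "\t") {
    df <- read.delim(file, sep = sep)
    need <- c("position_nt", "migration_center")
    if (!all(need %in% names(df)))
        stop(sprintf("'%s' must have columns: %s", file,
                     paste(need, collapse = ", ")))
    df[order(df$position_nt), ]
}

#' Read nucleosome core intervals from a BED-like table
#'
#' Three-column, header-less BED-like TSV (chrom, start, end). BED files
#' are 0-based half-open; set \code{zeroBased = FALSE} only if the file
#' already uses 1-based inclusive coordinates.
#'
#' @param file Path.
#' @param zeroBased Declare the coordinate convention (default TRUE =
#'   BED).
#' @return An \code{IRanges} of 1-based inclusive core intervals.
#' @export
readNucleosomeBed <- function(file, zeroBased = TRUE) {
    df <- read.delim(file, header = FALSE)
    if (ncol(df) < 3L) stop("BED-like file needs at least 3 columns")
    if (zeroBased) bedToIntervals(df[[2L]], df[[3L]])
    else IRanges::IRanges(start = as.integer(df[[2L]]),
                          end = as.integer(df[[3L]]))
}

#' Write a repair curve as TSV
#' @param curve A \linkS4class{RepairCurve}.
#' @param file Path.
#' @export
writeRepairCurve <- function(curve, file) {
    stopifnot(is(curve, "RepairCurve"))
    write.table(as.data.frame(curve), file, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(file)
}

#' Write a half-time profile as TSV
#'
#' Emits position, t_half, censored, smoothed and nucleosome label.
#'
#' @param profile A \linkS4class{THalfProfile}.
#' @param file Path.
#' @export
writeTHalfProfile <- function(profile, file) {
    stopifnot(is(profile, "THalfProfile"))
    write.table(as.data.frame(profile), file, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(file)
}
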