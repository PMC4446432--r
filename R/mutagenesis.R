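## Canavanine-resistance mutation frequency and MMS survival computation.

.checkCount <- function(x, what, minimum = 0) {
    if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
        stop(sprintf("'%s' must be finite numeric", what))
    if (any(x != floor(x)))
        stop(sprintf("'%s' must be whole colony counts; got %s", what,
            paste(format(x[x != floor(x)]), collapse = ", ")))
    if (any(x < minimum))
        stop(sprintf("'%s' must be >= %g", what, minimum))
    invisible(x)
}

#' Viable cell titer from a non-selective dilution plating
#'
#' Colonies counted on a non-selective plate after a fold-dilution of the
#' suspension give the viable cell count in the undiluted plated volume:
#' \code{titerColonies * titerDilution}.
#'
#' @param titerColonies Colony count on the non-selective plate (>= 1).
#' @param titerDilution Fold-dilution applied before plating (> 0).
#' @return Viable cells per plated volume.
#' @examples
#' viableTiter(100, 1e4)  # 1e6
#' @export
viableTiter <- function(titerColonies, titerDilution) {
    .checkCount(titerColonies, "titerColonies")
    if (any(titerColonies < 1))
        stop("zero titer colonies: viable titer is undefined")
    if (!is.numeric(titerDilution) || any(!is.finite(titerDilution)) ||
        any(titerDilution <= 0))
        stop("titerDilution must be positive")
    titerColonies * titerDilution
}

#' CAN1 forward-mutation frequency per viable cell
#'
#' Mutation frequency is the number of canavanine-resistant colonies per
#' viable cell plated on the selective medium. The denominator is the
#' viability-corrected cell count established by the non-selective titer of
#' the same suspension, so the estimate is invariant to the dilution chosen
#' for titering.
#'
#' @param selectiveColonies CanR colony count (integer >= 0).
#' @param titerColonies,titerDilution Non-selective titer of the same
#'   suspension (see \code{\link{viableTiter}}).
#' @return Mutants per viable cell (dimensionless; Table-style reporting
#'   multiplies by 1e6).
#' @examples
#' mutationFrequency(72, 1000, 1e4)  # 7.2e-06
#' @export
mutationFrequency <- function(selectiveColonies, titerColonies,
                              titerDilution) {
    .checkCount(selectiveColonies, "selectiveColonies")
    selectiveColonies / viableTiter(titerColonies, titerDilution)
}

#' Percent survival of treated relative to untreated cells
#'
#' Colony-forming titers of treated and untreated cultures at matched
#' dilutions; the untreated culture scores as 100 percent survival.
#'
#' @param treatedTiter,untreatedTiter Viable titers (untreated > 0).
#' @return Survival percentage.
#' @examples
#' survivalPercent(673, 1000)  # 67.3
#' @export
survivalPercent <- function(treatedTiter, untreatedTiter) {
    stopifnot(is.numeric(treatedTiter), is.numeric(untreatedTiter))
    if (any(!is.finite(untreatedTiter) | untreatedTiter <= 0))
        stop("untreated titer must be positive")
    if (any(!is.finite(treatedTiter) | treatedTiter < 0))
        stop("treated titer must be >= 0")
    100 * treatedTiter / untreatedTiter
}

#' Strain-by-treatment mutagenesis summary table
#'
#' Summarizes a plating-record table into the shape of a mutagenesis
#' report: per strain and MMS treatment, the mean and sample (n-1) standard
#' deviation of the CAN1 mutation frequency in 1e-6 units, and for treated
#' rows the percent survival (treated titer over the replicate-matched
#' untreated titer). Cells with a single replicate are emitted with an
#' \code{n1_flag}; empty strain-by-treatment groups are omitted with a
#' warning. The spread reported is the standard deviation, labeled as such.
#'
#' @param records data.frame with columns \code{strain}, \code{treated}
#'   (logical), \code{replicate}, \code{selective_colonies},
#'   \code{cells_plated_selective}, \code{titer_colonies},
#'   \code{titer_dilution}.
#' @return Long-format data.frame: strain, treated, n,
#'   mean_frequency_1e6, sd_frequency_1e6, mean_survival_pct,
#'   sd_survival_pct, n1_flag.
#' @export
mutagenesisTable <- function(records) {
    stopifnot(is.data.frame(records))
    need <- c("strain", "treated", "replicate", "selective_colonies",
              "cells_plated_selective", "titer_colonies", "titer_dilution")
    miss <- setdiff(need, names(records))
    if (length(miss))
        stop(sprintf("plating table lacks column(s): %s",
                     paste(miss, collapse = ", ")))
    records$frequency <- mutationFrequency(records$selective_colonies,
        records$titer_colonies, records$titer_dilution)
    records$titer <- viableTiter(records$titer_colonies,
                                 records$titer_dilution)
    out <- list()
    for (st in unique(records$strain)) {
        sub <- records[records$strain == st, ]
        unt <- sub[!sub$treated, ]
        for (tr in c(FALSE, TRUE)) {
            g <- sub[sub$treated == tr, ]
            if (!nrow(g)) {
                warning(sprintf(
                    "strain %s, treated = %s: no replicates; omitted",
                    st, tr))
                next
            }
            fr <- g$frequency * 1e6
            surv <- rep(NA_real_, nrow(g))
            if (tr && nrow(unt)) {
                m <- match(g$replicate, unt$replicate)
                surv <- ifelse(is.na(m), NA_real_,
                    survivalPercent(g$titer, unt$titer[m]))
            }
            out[[length(out) + 1L]] <- data.frame(
                strain = st, treated = tr, n = nrow(g),
                mean_frequency_1e6 = mean(fr),
                sd_frequency_1e6 = if (nrow(g) > 1L) sd(fr) else NA_real_,
                mean_survival_pct = if (tr) mean(surv, na.rm = TRUE)
                                    else 100,
                sd_survival_pct = if (tr && sum(!is.na(surv)) > 1L)
                                      sd(surv, na.rm = TRUE)
                                  else NA_real_,
                n1_flag = nrow(g) < 2L)
        }
    }
    if (!length(out)) stop("no usable strain/treatment groups")
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
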