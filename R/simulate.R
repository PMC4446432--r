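## Forward simulators producing every input the pipeline consumes, with
## known ground truth: Poisson lesions, first-order (chromatin-modulated)
## repair, enzymatic fragmentation, gel rendering, zero-class counting and
## plating counts. All simulators are reproducible given (seed, parameters).

.maybeSeed <- function(seed) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    invisible(NULL)
}

#' Simulate a Poisson lesion field on one molecule
#'
#' Draws a Poisson(rate * length / 1000) lesion count and places the
#' lesions uniformly without replacement on [1, length] (collisions are
#' avoided by sampling without replacement, i.e. re-drawn).
#'
#' @param lengthNt Molecule length in nt (> 0).
#' @param ratePerKb Lesion rate per kb (>= 0; 0 gives an empty field).
#' @param seed Optional integer seed.
#' @return A \linkS4class{LesionField}.
#' @examples
#' simulateLesions(50000, 1.0, seed = 1)
#' @export
simulateLesions <- function(lengthNt, ratePerKb, seed = NULL) {
    stopifnot(lengthNt > 0, ratePerKb >= 0)
    .maybeSeed(seed)
    n <- rpois(1L, ratePerKb * lengthNt / 1000)
    pos <- if (n > 0L) sort(sample.int(as.integer(lengthNt), n))
           else integer(0)
    new("LesionField", lengthNt = as.numeric(lengthNt), positions = pos,
        ratePerKb = as.numeric(ratePerKb))
}

#' Apply first-order repair to a lesion field
#'
#' Each lesion is removed independently with probability
#' \code{1 - exp(-k t)} by time t. A single removal time is drawn per
#' lesion from Exp(k), so the surviving sets are nested across increasing
#' times (a lesion repaired by an early time stays repaired).
#'
#' @param field A \linkS4class{LesionField}.
#' @param model A \linkS4class{RepairModel} whose \code{sitePositions}
#'   cover the field's lesions, or a numeric rate (scalar or per-lesion)
#'   in 1/min.
#' @param times Sampling times in minutes (>= 0).
#' @param seed Optional integer seed.
#' @return Named list (one element per time) of surviving lesion position
#'   vectors; at t = 0 all lesions survive.
#' @export
applyRepair <- function(field, model, times, seed = NULL) {
    stopifnot(is(field, "LesionField"), is.numeric(times))
    if (any(times < 0)) stop("negative repair time")
    pos <- field@positions
    k <- if (is(model, "RepairModel")) {
        i <- match(pos, model@sitePositions)
        if (anyNA(i))
            stop(sprintf("no repair rate for lesion position(s) %s",
                paste(pos[is.na(i)], collapse = ", ")))
        model@rateConstants[i]
    } else rep_len(as.numeric(model), length(pos))
    if (any(k < 0)) stop("repair rates must be >= 0")
    .maybeSeed(seed)
    removalTime <- rep(Inf, length(pos))
    active <- k > 0
    removalTime[active] <- rexp(sum(active), rate = k[active])
    out <- lapply(times, function(t) pos[removalTime > t])
    names(out) <- sprintf("t_%g", times)
    out
}

#' Fragment lengths produced by strand breaks on a molecule
#'
#' n breaks yield n + 1 fragments whose lengths sum exactly to the
#' molecule length. A break at position p separates [1, p] from
#' [p + 1, length].
#'
#' @param lengthNt Molecule length (nt).
#' @param breakPositions Integer positions in [1, lengthNt].
#' @return Integer vector of fragment lengths (zero-length fragments from
#'   a break at the last nucleotide are dropped; the sum is preserved).
#' @examples
#' fragmentsFromBreaks(100, c(10, 20, 30))  # 10 10 10 70
#' @export
fragmentsFromBreaks <- function(lengthNt, breakPositions) {
    stopifnot(lengthNt > 0)
    b <- as.numeric(breakPositions)
    if (length(b)) {
        bad <- b < 1 | b > lengthNt
        if (any(bad))
            stop(sprintf("break position(s) outside [1, %g]: %s", lengthNt,
                paste(format(b[bad]), collapse = ", ")))
        b <- sort(unique(b))
    }
    fr <- diff(c(0, b, lengthNt))
    fr[fr > 0]
}

#' Render fragment lengths as a densitometric lane profile
#'
#' Each fragment deposits a Gaussian band of width \code{bandSigma}
#' centered at its migration coordinate m(L) = a - b log10(L). With
#' \code{weights = "mass"} the band area is proportional to fragment
#' length (double-strand stain, one stain unit per nucleotide); with
#' \code{"count"} each fragment contributes unit area (end-labeled
#' detection, one label per molecule). Fragments outside the gel's
#' \code{lengthRange} run off (or never leave the well) and are dropped.
#' Additive zero-mean Gaussian noise with SD \code{noiseSd * max(noise-free
#' profile)} is applied last; it is deliberately not clipped, so noisy
#' profiles dip below zero around the baseline.
#'
#' Internally the fragment weights are accumulated onto the migration grid
#' (linear split between adjacent grid points) and convolved with the
#' Gaussian kernel, which is exact up to the grid step (default
#' \code{bandSigma / 5}).
#'
#' @param fragmentLengths Numeric fragment lengths (nt).
#' @param gel A \linkS4class{GelModel}.
#' @param label,enzymeTreated,timeMin Lane metadata.
#' @param weights \code{"mass"} or \code{"count"}.
#' @param noiseRef Optional reference intensity for the noise SD
#'   (\code{noiseSd * noiseRef}); a multi-lane simulation passes the peak
#'   of a common reference lane so one scan has one absolute noise floor.
#'   By default the lane's own noise-free peak is used.
#' @param seed Optional integer seed (noise only).
#' @return A \linkS4class{LaneProfile}.
#' @export
renderLane <- function(fragmentLengths, gel, label = "sim",
                       enzymeTreated = NA, timeMin = NA_real_,
                       weights = c("mass", "count"), noiseRef = NULL,
                       seed = NULL) {
    stopifnot(is(gel, "GelModel"), is.numeric(fragmentLengths))
    weights <- match.arg(weights)
    L <- fragmentLengths[fragmentLengths >= gel@lengthRange[1L] &
                         fragmentLengths <= gel@lengthRange[2L]]
    sig <- gel@bandSigma
    dm <- gel@gridStep
    mLo <- migrationOf(gel, gel@lengthRange[2L]) - 4 * sig
    mHi <- migrationOf(gel, gel@lengthRange[1L]) + 4 * sig
    grid <- seq(mLo, mHi, by = dm)
    nG <- length(grid)
    h <- numeric(nG)
    if (length(L)) {
        ## aggregate integer lengths first: one band per distinct length
        li <- as.integer(round(L))
        cnt <- tabulate(li, nbins = max(li))
        uniq <- which(cnt > 0L)
        w <- if (weights == "mass") as.numeric(uniq) * cnt[uniq]
             else as.numeric(cnt[uniq])
        m <- migrationOf(gel, uniq)
        fi <- (m - mLo) / dm
        i0 <- pmin(pmax(floor(fi) + 1L, 1L), nG - 1L)
        fr <- fi - (i0 - 1L)
        fr <- pmin(pmax(fr, 0), 1)
        h <- h + unname(tapply(w * (1 - fr), factor(i0, levels = seq_len(nG)),
                               sum, default = 0))
        h <- h + unname(tapply(w * fr, factor(i0 + 1L, levels = seq_len(nG)),
                               sum, default = 0))
    }
    kHalf <- ceiling(4 * sig / dm)
    kern <- dnorm(seq(-kHalf, kHalf) * dm, 0, sig)
    y <- stats::convolve(h, rev(kern), type = "open")
    y <- y[(kHalf + 1L):(kHalf + nG)]
    y[y < 0] <- 0    # FFT ringing
    if (gel@noiseSd > 0) {
        ## zero-mean detector noise: never clipped, or rectified noise
        ## would masquerade as stain mass across the whole lane
        .maybeSeed(seed)
        ref <- if (is.null(noiseRef)) max(y) else noiseRef
        y <- y + rnorm(nG, 0, gel@noiseSd * ref)
    }
    LaneProfile(migration = grid, intensity = y, label = label,
                enzymeTreated = enzymeTreated, timeMin = timeMin)
}

#' Exact size ladder under a gel model
#'
#' Calibration pairs generated from the gel's own migration law. Because
#' the law is linear in log10(length) and \code{\link{fitLadder}}
#' interpolates linearly in log10(length), a two-knot exact ladder already
#' reproduces the law everywhere.
#'
#' @param gel A \linkS4class{GelModel}.
#' @param lengths Ladder fragment lengths (nt), any order.
#' @return A \linkS4class{SizeLadder}.
#' @export
exactLadder <- function(gel, lengths = c(1e5, 1e4, 1e3, 1e2, 10, 1)) {
    stopifnot(is(gel, "GelModel"))
    lengths <- sort(unique(lengths), decreasing = TRUE)
    SizeLadder(migration = migrationOf(gel, lengths), lengthNt = lengths)
}

#' Simulate zero-class (intact/cut) counting of restriction fragments
#'
#' Each of n fragments carries Poisson(mu) lesions, so it is intact with
#' probability exp(-mu); the intact count is binomial.
#'
#' @param muTrue Mean lesions per fragment (>= 0).
#' @param nMolecules Number of fragments scored (>= 1).
#' @param seed Optional integer seed.
#' @return List with \code{intact} and \code{total} counts.
#' @examples
#' simulateRestrictionAssay(1, 1e4, seed = 1)$intact / 1e4  # ~ exp(-1)
#' @export
simulateRestrictionAssay <- function(muTrue, nMolecules, seed = NULL) {
    stopifnot(muTrue >= 0, nMolecules >= 1)
    .maybeSeed(seed)
    list(intact = rbinom(1L, as.integer(nMolecules),
                         expectedZeroFraction(muTrue)),
         total = as.integer(nMolecules))
}

#' Simulate a Southern zero-class repair time course
#'
#' Thinned-Poisson kinetics: if a fraction s(t) of the initial lesions
#' survives at time t, the burden is still Poisson with mean
#' \code{mu0 * s(t)}, so the intact count at each time is binomial with
#' probability \code{exp(-mu0 * s(t))}. Band signals mirror the blot: the
#' +enzyme full-length band is the intact count, the -enzyme band the
#' total count.
#'
#' @param mu0 Initial mean lesions per fragment (> 0).
#' @param survivingFraction Fraction of initial lesions remaining at each
#'   time (1 at t = 0).
#' @param timesMin Times (minutes), first = 0.
#' @param nMolecules Fragments scored per time point.
#' @param seed Optional integer seed.
#' @return data.frame with time_min, band_plus (intact), band_minus
#'   (total) and the generating mu_true per time.
#' @export
simulateFragmentTimecourse <- function(mu0, survivingFraction, timesMin,
                                       nMolecules, seed = NULL) {
    stopifnot(mu0 > 0, length(survivingFraction) == length(timesMin),
              all(survivingFraction >= 0), all(survivingFraction <= 1),
              survivingFraction[1L] == 1, timesMin[1L] == 0)
    .maybeSeed(seed)
    muT <- mu0 * survivingFraction
    intact <- rbinom(length(muT), as.integer(nMolecules),
                     expectedZeroFraction(muT))
    data.frame(time_min = timesMin, band_plus = intact,
               band_minus = as.integer(nMolecules), mu_true = muT)
}

#' Simulate a full genomic alkaline-gel repair experiment
#'
#' Forward model behind the genomic BER assay: each molecule receives
#' Poisson lesions at \code{ratePerKb}; a programmed fraction of lesions
#' is removed by each time (one uniform draw per lesion, so surviving sets
#' are nested); every surviving lesion is converted to a strand break
#' (complete AAG/APE1 cleavage, or partial via \code{cleavageProb}); the
#' fragment pool of the +enzyme lane and the intact molecules of the
#' no-enzyme control lane are rendered as mass-stained lane profiles.
#'
#' @param nMolecules Molecules per lane.
#' @param moleculeLengthNt Molecule length (nt).
#' @param ratePerKb True lesion density (per kb).
#' @param removedFraction Fraction of initial lesions removed by each time
#'   (0 at t = 0, non-decreasing).
#' @param timesMin Times (minutes), first = 0.
#' @param gel A \linkS4class{GelModel}.
#' @param cleavageProb Per-lesion cleavage probability (default 1,
#'   complete digestion).
#' @param seed Optional integer seed.
#' @return List: \code{lanes} (a (+, -) \linkS4class{LaneProfile} pair per
#'   time), \code{ladder} (exact \linkS4class{SizeLadder}), \code{truth}
#'   (generating parameters).
#' @export
simulateGenomicAssay <- function(nMolecules, moleculeLengthNt, ratePerKb,
                                 removedFraction, timesMin, gel,
                                 cleavageProb = 1, seed = NULL) {
    stopifnot(length(removedFraction) == length(timesMin),
              timesMin[1L] == 0, removedFraction[1L] == 0,
              all(diff(removedFraction) >= 0),
              all(removedFraction >= 0), all(removedFraction < 1),
              cleavageProb > 0, cleavageProb <= 1,
              is(gel, "GelModel"))
    .maybeSeed(seed)
    n <- as.integer(nMolecules)
    L <- as.integer(moleculeLengthNt)
    nT <- length(timesMin)
    lam <- ratePerKb * L / 1000
    counts <- rpois(n, lam)
    fragLists <- lapply(seq_len(nT), function(j) vector("list", n))
    for (i in seq_len(n)) {
        ni <- counts[i]
        if (ni == 0L) {
            for (j in seq_len(nT)) fragLists[[j]][[i]] <- L
            next
        }
        p <- sort(sample.int(L, ni))
        u <- runif(ni)
        cut <- if (cleavageProb < 1) runif(ni) < cleavageProb
               else rep(TRUE, ni)
        for (j in seq_len(nT)) {
            b <- p[u >= removedFraction[j] & cut]
            fragLists[[j]][[i]] <- if (length(b)) diff(c(0L, b, L)) else L
        }
    }
    ## render noise-free, then apply ONE absolute noise floor to the whole
    ## gel (one scanner, one scan), referenced to the brightest +enzyme
    ## (analyte) lane
    gel0 <- initialize(gel, noiseSd = 0)
    lanes <- vector("list", 2L * nT)
    for (j in seq_len(nT)) {
        t <- timesMin[j]
        lanes[[2L * j - 1L]] <- renderLane(unlist(fragLists[[j]]), gel0,
            label = sprintf("plus_t%g", t), enzymeTreated = TRUE,
            timeMin = t, weights = "mass")
        lanes[[2L * j]] <- renderLane(rep(L, n), gel0,
            label = sprintf("minus_t%g", t), enzymeTreated = FALSE,
            timeMin = t, weights = "mass")
    }
    if (gel@noiseSd > 0) {
        ref <- max(vapply(lanes[seq(1L, 2L * nT, by = 2L)],
                          function(l) max(intensity(l)), numeric(1)))
        lanes <- lapply(lanes, function(l)
            initialize(l, intensity = intensity(l) +
                rnorm(length(intensity(l)), 0, gel@noiseSd * ref)))
    }
    list(lanes = lanes, ladder = exactLadder(gel),
         truth = list(rate_per_kb = ratePerKb,
                      removed_fraction = removedFraction,
                      times_min = timesMin))
}

#' Simulate an end-labeled sequencing-gel repair experiment
#'
#' Forward model behind the high-resolution assay: per molecule, a lesion
#' is drawn at each damage site with its site-specific probability and
#' repaired with first-order kinetics (one Exp(k) removal time per
#' lesion). At each sampling time the end-labeled cleavage chemistry sees
#' only the lesion NEAREST the labeled end: the molecule contributes a
#' band at that site's distance, or the full-length band when no lesion
#' survives. Lanes are rendered with count-proportional band areas
#' (end-labeled detection).
#'
#' @param sitePositions Damage-site positions (nt from the labeled end),
#'   strictly increasing, within [1, fragmentLengthNt].
#' @param damageProb Per-site lesion probability (scalar or per-site).
#' @param repairModel A \linkS4class{RepairModel} for the sites.
#' @param timesMin Times (minutes), first = 0.
#' @param gel A \linkS4class{GelModel}.
#' @param nMolecules Labeled molecules per lane.
#' @param fragmentLengthNt Restriction fragment length (default 1144 nt).
#' @param seed Optional integer seed.
#' @return List: \code{lanes} (one \linkS4class{LaneProfile} per time),
#'   \code{centers} (band registry: migration center per site plus the
#'   full-length band, in band order), \code{counts} (the true
#'   molecule-count \linkS4class{BandKineticsTable}), \code{truth}
#'   (data.frame position, k, t_half_min).
#' @export
simulateSequencingGel <- function(sitePositions, damageProb, repairModel,
                                  timesMin, gel, nMolecules,
                                  fragmentLengthNt = 1144, seed = NULL) {
    stopifnot(is(repairModel, "RepairModel"), is(gel, "GelModel"),
              timesMin[1L] == 0, !is.unsorted(sitePositions,
                                              strictly = TRUE))
    sites <- as.integer(sitePositions)
    S <- length(sites)
    if (min(sites) < 1L || max(sites) > fragmentLengthNt)
        stop("site positions must lie within [1, fragmentLengthNt]")
    p <- rep_len(damageProb, S)
    stopifnot(all(p >= 0), all(p <= 1))
    i <- match(sites, repairModel@sitePositions)
    if (anyNA(i)) stop("repairModel lacks rates for some sites")
    k <- repairModel@rateConstants[i]
    .maybeSeed(seed)
    n <- as.integer(nMolecules)
    ## lesion list: (molecule, site index, removal time)
    mol <- integer(0); siteIdx <- integer(0); rt <- numeric(0)
    for (j in seq_len(S)) {
        m <- which(runif(n) < p[j])
        if (!length(m)) next
        mol <- c(mol, m)
        siteIdx <- c(siteIdx, rep(j, length(m)))
        rt <- c(rt, if (k[j] > 0) rexp(length(m), k[j])
                    else rep(Inf, length(m)))
    }
    ## nearest surviving lesion per molecule at each time
    ord <- order(siteIdx)           # ascending position = nearest first
    mol <- mol[ord]; siteIdx <- siteIdx[ord]; rt <- rt[ord]
    nT <- length(timesMin)
    countMat <- matrix(0, nrow = S, ncol = nT)
    fullLen <- numeric(nT)
    lanes <- vector("list", nT)
    for (jt in seq_len(nT)) {
        alive <- rt > timesMin[jt]
        mA <- mol[alive]; sA <- siteIdx[alive]
        first <- !duplicated(mA)    # nearest site per molecule
        countMat[, jt] <- tabulate(sA[first], nbins = S)
        fullLen[jt] <- n - sum(first)
        fragLens <- c(rep(sites, countMat[, jt]),
                      rep(fragmentLengthNt, fullLen[jt]))
        lanes[[jt]] <- renderLane(fragLens, gel,
            label = sprintf("seq_t%g", timesMin[jt]), enzymeTreated = TRUE,
            timeMin = timesMin[jt], weights = "count")
    }
    counts <- BandKineticsTable(positions = sites, timesMin = timesMin,
        intensities = countMat, fullLength = fullLen,
        fragmentLengthNt = fragmentLengthNt)
    list(lanes = lanes,
         centers = migrationOf(gel, c(sites, fragmentLengthNt)),
         counts = counts,
         truth = data.frame(position_nt = sites, k_per_min = k,
             t_half_min = ifelse(k > 0, log(2) / k, Inf),
             damage_prob = p))
}

#' Study design for the high-resolution repair simulation
#'
#' The reference configuration of the sequencing-gel simulation: 50 damage
#' sites spread over a 1144-nt end-labeled restriction fragment carrying
#' five prominent positioned nucleosomes (147-nt cores, ~60-nt linkers);
#' sites inside a core repair slowly (half-times 120-240 min), linker
#' sites fast (30-90 min); a low per-site damage probability (0.001,
#' about 0.05 lesions per fragment) keeps the end-labeled runoff geometry
#' in its linear regime, where proximal lesions rarely shadow distal
#' bands. Per-site half-times are drawn uniformly within their class.
#'
#' @param nSites Number of damage sites.
#' @param fragmentLengthNt Fragment length (nt).
#' @param seed Optional integer seed for the half-time draw.
#' @return Named list: sites, coreIntervals (\code{IRanges}), inCore,
#'   tHalfTrue, repairModel, damageProb, nMolecules, timesMin, gel,
#'   bandSigma, fragmentLengthNt.
#' @export
hiresStudyDesign <- function(nSites = 50L, fragmentLengthNt = 1144L,
                             seed = NULL) {
    .maybeSeed(seed)
    sites <- as.integer(round(seq(120, 1120, length.out = nSites)))
    cores <- IRanges::IRanges(start = as.integer(seq(150, 978, by = 207)),
                              width = 147L)
    inCore <- IRanges::overlapsAny(IRanges::IRanges(sites, width = 1L),
                                   cores)
    tHalfTrue <- ifelse(inCore, runif(nSites, 120, 240),
                        runif(nSites, 30, 90))
    list(sites = sites, coreIntervals = cores, inCore = inCore,
         tHalfTrue = tHalfTrue,
         repairModel = RepairModel(sites,
                                   rateConstants = log(2) / tHalfTrue),
         damageProb = 0.001, nMolecules = 5e6,
         timesMin = c(0, 30, 60, 120, 240, 480),
         gel = GelModel(bandSigma = 0.06, lengthRange = c(50, 1200)),
         bandSigma = 0.06,
         fragmentLengthNt = as.integer(fragmentLengthNt))
}

#' Simulate a canavanine-mutagenesis plating experiment
#'
#' Binomial survivors of the treatment, binomial mutants among the
#' survivors plated selectively, and a Poisson-sampled non-selective titer
#' at the stated dilution.
#'
#' @param nCells Cells plated on the selective medium (nominal count).
#' @param mutantFrequency Mutants per viable cell, in [0, 1].
#' @param survivalFraction Treatment survival, in (0, 1].
#' @param dilution Fold-dilution of the non-selective titer plating.
#' @param seed Optional integer seed.
#' @return One-row data.frame in the plating-record layout:
#'   selective_colonies, cells_plated_selective, titer_colonies,
#'   titer_dilution.
#' @examples
#' simulatePlating(1e8, 7.2e-6, 1, 1e6, seed = 1)
#' @export
simulatePlating <- function(nCells, mutantFrequency, survivalFraction,
                            dilution, seed = NULL) {
    stopifnot(nCells >= 1, mutantFrequency >= 0, mutantFrequency <= 1,
              survivalFraction > 0, survivalFraction <= 1, dilution > 0)
    .maybeSeed(seed)
    survivors <- rbinom(1L, as.integer(nCells), survivalFraction)
    mutants <- rbinom(1L, survivors, mutantFrequency)
    titer <- rpois(1L, survivors / dilution)
    data.frame(selective_colonies = mutants,
               cells_plated_selective = as.numeric(nCells),
               titer_colonies = titer, titer_dilution = dilution)
}
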