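---
title: "Quantifying methylpurine damage and repair kinetics from gel densitometry"
author: "lesionKinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying methylpurine damage and repair kinetics from gel densitometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionKinetics)
```

# The measurement problem

Methyl methanesulfonate (MMS) methylates purines in genomic DNA
(7-methylguanine, 3-methyladenine); base excision repair removes them.
None of this is directly visible on a gel. The trick common to all the
assays in this package is enzymatic conversion: purified DNA is treated
in vitro with a glycosylase plus AP endonuclease (AAG/APE1), which turns
every methylpurine into a single-strand break. Fragment-size distributions
on denaturing (alkaline) gels then carry the lesion counts, and comparing
the enzyme-treated aliquot with a mock-treated aliquot of the same sample
isolates the enzyme-dependent (lesion-specific) breaks from background
fragmentation.

Three assays share this principle at different resolutions, and a fourth
quantifies the biological consequence:

1. **Genomic (ensemble-average) assay.** Whole genomic DNA on an alkaline
   gel, stained with a mass-proportional dye and quantified as a lane
   profile. The number-average fragment length summarizes the break
   frequency genome-wide.
2. **Restriction-fragment (zero-class) assay.** A Southern blot of one
   restriction fragment (e.g. the ~2.2 kb GAL10 fragment). Only intact
   fragments contribute to the full-length band; Poisson statistics
   convert the intact fraction to a mean lesion burden.
3. **High-resolution sequencing-gel assay.** An end-labeled restriction
   fragment (the 1144-bp RPB2 DraI fragment) cleaved at surviving lesions
   gives one band per damage site; band kinetics across a repair time
   course give per-nucleotide repair half-times, overlaid on nucleosome
   positions.
4. **Mutagenesis and survival.** Canavanine-resistance (CAN1 forward
   mutation) frequencies and colony-forming survival from plating counts.

No raw data from such experiments are deposited anywhere in machine-
readable form; all primary measurements are gel images. The package
therefore pairs every analysis stage with a forward simulator
(`simulateGenomicAssay()`, `simulateRestrictionAssay()`,
`simulateSequencingGel()`, `simulatePlating()`) that produces the same
inputs with known ground truth, so the whole chain is validated by
parameter recovery rather than by re-reading figures.

# Models and estimators

## Zero-class Poisson statistics

Lesions land on fragments as a Poisson process, so a fragment of mean
burden $\mu$ is intact with probability $P_0 = e^{-\mu}$, and

$$\mu = -\ln P_0, \qquad \text{lesions/kb} = \frac{1000\,\mu}{L}.$$

`zeroClassMu()` and `expectedZeroFraction()` are this inverse pair;
`perKb()` rescales by fragment length. $P_0$ is measured as the ratio of
full-length band volumes in the (+enzyme)/(−enzyme) aliquot pair of the
same digest (`zeroClassFraction()`). Blot noise routinely yields ratios
slightly above 1; ratios in $(1, 1.05]$ are clamped to 1 with a QC flag,
anything larger is treated as a pairing/loading error and refused —
silent clamping of gross errors would hide calibration problems.

## Ensemble-average fragment length

With a mass-proportional stain, a profile sample of intensity $I_i$ at
fragment length $L_i$ represents $I_i/L_i$ molecules, so the
number-average fragment length of a lane is

$$L_n = \frac{\sum_i I_i}{\sum_i I_i / L_i},$$

total mass over total molecule count (`ensembleAverageLength()`). Its
reciprocal measures breaks per nucleotide plus the finite-molecule term
$1/L$; subtracting the no-enzyme control lane in reciprocal space
(`lesionFrequency()`) removes both that term and background
fragmentation:

$$\text{lesions/kb} = 1000\left(\frac{1}{L_n^{+}} - \frac{1}{L_n^{-}}\right).$$

Lengths come from a ladder calibration, piecewise-linear in
$\log_{10}(L)$ versus migration (`fitLadder()`): it reproduces the knots
exactly, is deterministic, and is the standard gel-sizing model. Queries
beyond the outermost knots extrapolate linearly and are flagged.

The estimator is a discrete sum over profile samples (no resampling),
assuming approximately uniform migration sampling. Negative corrected
frequencies are reported with a QC flag, never zeroed: they are
information about measurement noise.

## Repair curves and half-times

Percent repair at time $t$ is $100\,(\mu_0 - \mu_t)/\mu_0$
(`percentRepair()`); values outside $[0, 100]$ are reported as-is.
Per-position repair half-times are interpolated at the first downward
crossing of 0.5 in the fraction-remaining series, linearly in
$\log(\text{fraction})$ versus time (`interpolateHalfTime()`). First-order
repair kinetics is the implicit model of all these assays, and under it
the fraction decays exponentially, making the log-linear estimator
*exact* on any sampling grid that brackets the crossing — this is also
what the half-time exactness checks in the test suite verify to 1e-9.
How the original analyses interpolated between sampled times is not
stated anywhere we could find; log-linear is this package's declared
choice. Series that never reach 0.5 are censored, not extrapolated. When
the lower bracketing fraction is exactly zero the log-linear formula
degenerates and that segment falls back to linear interpolation.

## Sequencing-gel deconvolution and smoothing

Neighboring bands on a sequencing gel overlap. `deconvolveLane()` fits
the profile as a non-negative sum of Gaussians with *fixed centers* (the
band registry) and a *single shared width*: with both fixed, the fit is a
convex non-negative least-squares problem with a deterministic solution
and no initialization sensitivity (solved by `pracma::lsqnonneg`).
Per-band widths and center refinement are deliberately out of scope.
Centers closer than $0.1\sigma$ make the design ill-conditioned and are
refused.

`fractionRemaining()` normalizes each lane by its **total** signal (all
damage bands plus the full-length band) to correct loading — total
labeled DNA per lane is the natural loading proxy, though the original
analyses do not state their denominator — then divides each position by
its $t=0$ value. Positions with zero $t=0$ signal are marked unusable
rather than aborting.

`smoothProfile()` averages half-times over a 41-nt window in *sequence
coordinates* (the position plus 20 nt on each side): damage sites
(purines) are irregularly spaced, so an index-based window would not be a
fixed number of nucleotides. Censored sites are excluded from the
average, not imputed at the longest time — imputation would bias the
profile low exactly where repair is slowest. Near fragment ends the
window truncates. `annotateNucleosomes()` labels positions core/linker
from supplied 1-based inclusive intervals (BED-like 0-based half-open
input is converted by `bedToIntervals()`/`readNucleosomeBed()`).

## Mutagenesis

Mutation frequency is mutants per viable cell:
`selective_colonies / (titer_colonies × titer_dilution)`, which makes the
estimate invariant to the dilution chosen for titering. It is a
*frequency*, not a per-generation rate — no fluctuation (Luria–Delbrück)
correction is applied, matching how such tables are reported. Survival is
the colony-forming titer of treated cells relative to untreated cells
scored as 100%. Replicate spread is the sample (n−1) standard deviation,
labeled as such: independent experiments are a sample, not a population.
Colony counts must be whole numbers; fractional inputs are rejected.

# The forward simulators

`simulateLesions()` draws a Poisson lesion count at the requested rate
and places lesions uniformly without replacement. `applyRepair()` draws
one exponential removal time per lesion, so surviving sets are nested
across times under a single random stream — a testable monotonicity
property. Cleavage is complete by default (every surviving lesion becomes
a break); a per-lesion cleavage probability is available to probe
robustness. `fragmentsFromBreaks()` conserves total length exactly.

`renderLane()` uses the migration law $m(L) = a - b\log_{10} L$ (defaults
$a = 100$, $b = 30$), Gaussian bands of fixed width, and mass- or
count-proportional band areas (double-strand stain versus end-labeled
detection). Fragment weights are accumulated onto the migration grid and
convolved with the Gaussian kernel. Band width is constant across the
lane — a declared simplification; real denaturing-gel band width varies
with length.

Two rendering choices deserve explanation because they decide what the
recovery tests can honestly show:

* **Rendered length range.** The default `lengthRange` is wide
  (`c(1, 2e5)` nt) so that an *ideal* lane records every fragment. At
  1 lesion/kb roughly 5% of fragments are shorter than 50 nt; a gel that
  loses them biases the reciprocal ensemble length by about the same
  amount, which would swamp the 2% recovery the ensemble-average oracle
  checks. Real-gel resolution limits are instead expressed on the
  analysis side through `lengthBounds`: noise-free ideal lanes are
  analyzed over the full range, noisy lanes over `c(100, 2e5)` (below
  ~100 nt the simulated signal sits under the noise floor), and the
  conservative default of `ensembleAverageLength()` stays
  `c(500, 2e5)` for real data, where the short-length tail is usually
  pure noise amplified by $1/L$.
* **One noise floor per gel.** Detector noise belongs to the scan, not to
  the lane: `simulateGenomicAssay()` renders all lanes noise-free and
  adds a single absolute Gaussian noise level (`noiseSd` × the peak of
  the brightest enzyme-treated lane) to every lane. Scaling noise to each
  lane's own peak would make the no-enzyme control — all of its mass in
  one tight band — by far the noisiest measurement in the experiment,
  which is the opposite of how scanners behave. Noise is zero-mean and
  never clipped at zero: rectified noise would masquerade as stain mass
  across the whole lane. Consequently raw noisy profiles dip below zero
  around the baseline; `subtractBackground()` clips after baseline
  removal.

A lane whose $1/L$-weighted count signal is indistinguishable from zero
(a noise-dominated intact control) would otherwise produce a meaningless
or negative $L_n$; `ensembleAverageLength()` censors such lanes at the
upper length bound and flags them, reading "no fragmentation detectable
at this gel's resolution".

`simulateSequencingGel()` reproduces the end-labeled runoff geometry:
per molecule, only the surviving lesion *nearest the labeled end* is
seen, or the full-length band if none survives. Proximal lesions
therefore shadow distal bands, and because `fractionRemaining()` applies
no shadowing correction (band ratios only), the distal fraction remaining
is inflated by roughly $\exp\!\big(\sum_{j \text{ proximal}} p_j
(1-s_j(t))\big)$ as proximal sites repair. The reference study design
(`hiresStudyDesign()`) therefore uses a low per-site damage probability
(0.001, about 0.05 lesions per fragment) so this term stays within a few
percent — the linear regime in which the band-ratio analysis is valid —
and 5×10^6 labeled molecules per lane so that per-band counting noise
(~2% per band) translates into half-time errors of a few percent. Under
these conditions, recovery is 98–100% of sites within 10% of the true
half-time and Spearman correlation ≈ 0.99 between smoothed recovered and
true profiles. At substantially higher lesion densities the uncorrected
band-ratio method *systematically overestimates* distal half-times; that
regime is reachable with the same simulator and is a useful way to
explore the method's limits, but it is not a regime in which the
uncorrected estimator should be trusted.

## Reference study conditions

The defaults encode one fixed set of study conditions rather than tuned
knobs:

| quantity | value | note |
|---|---|---|
| genomic molecule length | 50 kb | high-MW genomic prep |
| initial lesion density | 1.0 /kb | MMS-dose scale of the genomic assay |
| programmed repair | 0, 40, 70, 85% at 0, 60, 120, 240 min | genomic time course |
| lane noise | 1% of the reference peak | noisy-recovery conditions |
| Southern fragment | 2200 nt, mu = 1.1 | zero-class assay |
| high-res fragment | 1144 nt, 50 sites, 5 cores | `hiresStudyDesign()` |
| per-site half-times | 120–240 min (core), 30–90 min (linker) | uniform within class |
| sampling times (high-res) | 0, 30, 60, 120, 240, 480 min | brackets all crossings |
| band width / separation | sigma 0.06, adjacent centers ≥ 3 sigma | convex NNLS well-posed |
| mutagenesis | 7.2×10⁻⁶, 10⁸ cells, titer ~10³ colonies | plating recovery |

Simulation sizes (10^5 molecules for the ensemble oracle, 2×10^4 per lane
across 20 seeds for the noisy time course, 5×10^6 for the sequencing gel,
1000 plating replicates) are the package's chosen problem sizes: large
enough that sampling error sits well below each stage's tolerance, small
enough to run on a laptop in a couple of minutes.

# What the simulations do and do not show

The generators emulate Poisson lesion placement, first-order
chromatin-modulated repair, complete enzymatic cleavage, log-linear
electrophoresis with Gaussian bands, white detector noise, and binomial
plating. They do **not** emulate sequence-specific methylation chemistry
(7mG versus 3mA propensities), partial digestion unless asked, saturation
or nonlinear detector response, band-width variation along the gel,
gel-to-gel migration warping, or replication and growth during recovery.
Passing recovery tests therefore demonstrates that the estimators are
correct and well-conditioned under the stated physics — not that any
particular biological dataset meets those assumptions. The no-enzyme
correction, QC flags for negative frequencies and clamped ratios, and the
censoring rules are the package's handles for real-data deviations.

# Numerical and degenerate-input policy

* Ties/ambiguity: the *first* downward crossing defines the half-time in
  non-monotone series; deterministic by construction.
* $P_0 = 1$ maps to $\mu = 0$ (an undamaged sample is valid input);
  $P_0 > 1.05$ and $P_0 \le 0$ are refused with the offending value named.
* A zero-signal lane within the analysis bounds is an error; a zero
  $t=0$ band marks only that position unusable.
* All simulators are bit-reproducible given (seed, parameters); repair
  survival draws one removal time per lesion so time-nesting is exact.
* Coordinates are 1-based inclusive internally; BED-like inputs must be
  declared and are converted on read.

# A worked miniature

```{r mini, eval = FALSE}
## simulate a small genomic repair experiment and quantify it
gel <- GelModel(bandSigma = 1, noiseSd = 0, lengthRange = c(1, 2e5),
                gridStep = 1)
sim <- simulateGenomicAssay(nMolecules = 2e4, moleculeLengthNt = 5e4,
                            ratePerKb = 1.0,
                            removedFraction = c(0, 0.4, 0.7, 0.85),
                            timesMin = c(0, 60, 120, 240),
                            gel = gel, seed = 1)
rc <- genomicTimecourse(sim$lanes, sim$ladder, lengthBounds = c(1, 2e5))
rc
```

The full-size recovery runs — including the complete high-resolution
chain — live in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`; every number this vignette quotes (recovery
within 2%, 98–100% of sites within 10%, Spearman ≈ 0.99) is computed
there, not asserted here.
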