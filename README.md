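# lesionKinetics

Quantification of DNA alkylation damage (methylpurines) and base excision
repair (BER) kinetics in yeast from one-dimensional gel densitometry — for
researchers who measure repair with AAG/APE1-cleavage gel assays and
want the downstream quantification to be explicit, tested and
reproducible.

MMS-induced 7-methylguanine and 3-methyladenine are invisible on a gel
until a glycosylase + AP endonuclease (AAG/APE1) treatment converts each
lesion into a single-strand break. Fragment-size distributions on
alkaline gels then carry the lesion counts. The package implements the
three quantification methods built on that conversion, plus the
mutagenesis readout:

* **Genomic ensemble-average assay** — the number-average fragment length
  of a mass-stained lane, `Ln = Σ I / Σ (I/L)`, corrected by the
  no-enzyme control lane in reciprocal space:
  `lesions/kb = 1000 (1/Ln⁺ − 1/Ln⁻)`.
* **Zero-class (Poisson) restriction-fragment assay** — from the intact
  full-length band fraction of a Southern blot, `mu = −ln(P0)`,
  `lesions/kb = 1000 mu / L`.
* **High-resolution per-nucleotide repair mapping** — non-negative
  least-squares deconvolution of overlapping sequencing-gel bands
  (fixed centers, shared Gaussian width), loading-corrected fractions
  remaining, per-site repair half-times `t0.5` by log-linear
  interpolation (exact for first-order repair), 41-nt positional
  smoothing, and nucleosome core/linker annotation.
* **Mutagenesis and survival** — canavanine-resistance mutation frequency
  per viable cell (`CanR colonies / (titer colonies × dilution)`) and
  percent survival relative to untreated cultures.

Because the primary data of such studies are gel images with no deposited
machine-readable form, every analysis stage is paired with a forward
simulator with known ground truth (Poisson lesions, first-order
chromatin-modulated repair, enzymatic fragmentation, gel rendering with
Gaussian bands and detector noise, zero-class counting, binomial
plating), so the whole pipeline is validated by parameter recovery.

## Worked example

Simulate a genomic repair time course (50 kb molecules, 1 lesion/kb,
programmed removal of 40/70/85% at 60/120/240 min), render ideal alkaline
gel lanes, and quantify them back:

```r
library(lesionKinetics)

gel <- GelModel(bandSigma = 1, noiseSd = 0, lengthRange = c(1, 2e5),
                gridStep = 1)
sim <- simulateGenomicAssay(nMolecules = 2e4, moleculeLengthNt = 5e4,
                            ratePerKb = 1.0,
                            removedFraction = c(0, 0.4, 0.7, 0.85),
                            timesMin = c(0, 60, 120, 240),
                            gel = gel, seed = 1)
rc <- genomicTimecourse(sim$lanes, sim$ladder, lengthBounds = c(1, 2e5))
rc
#> RepairCurve: 4 time points, initial 1.004 lesions/kb
#>  time_min percent_repair lesions_per_kb
#>         0           0.00         1.0040
#>        60          40.04         0.6020
#>       120          70.03         0.3009
#>       240          85.01         0.1506
```

The recovered initial density (1.004 lesions/kb) and repair percentages
(40.04, 70.03, 85.01) match the programmed truth to a fraction of a
percent — the enzyme/no-enzyme correction removes the finite-length term
exactly in expectation.

The zero-class route, on a band pair from a 2.2 kb Southern fragment:

```r
p0 <- zeroClassFraction(bandPlus = 36.79, bandMinus = 100)
zeroClassMu(as.numeric(p0))          # 0.9999 lesions per fragment
perKb(zeroClassMu(as.numeric(p0)), 2200)  # 0.4545 lesions/kb
```

For the high-resolution chain see `?hiresStudyDesign`,
`?simulateSequencingGel`, `?deconvolveKinetics`, `?tHalfProfile` and the
vignette (`vignettes/lesion-repair-kinetics.Rmd`), which documents the
models, the estimators, the study conditions and their limits.

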