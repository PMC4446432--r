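Package: lesionKinetics
Title: Quantification of Base Excision Repair Kinetics from Gel Densitometry
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify alkylation damage (methylpurine) loads and
    base excision repair kinetics in yeast from one-dimensional gel
    densitometry. Implements ensemble-average (number-average) fragment-length
    analysis of alkaline gels corrected by a no-enzyme control lane,
    zero-class Poisson analysis of restriction-fragment Southern blots
    (mu = -ln(P0)), high-resolution per-nucleotide repair half-times from
    sequencing-gel band deconvolution with nucleosome annotation, and
    canavanine-resistance mutation frequency / MMS survival computation.
    A forward simulator generates every input the pipeline consumes with
    known ground truth so each stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    pracma,
    IRanges,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
biocViews: Epigenetics, DNADamage, Software
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'fragment-assay.R'
    'gel-densitometry.R'
    'highres-repair.R'
    'io.R'
    'lesionKinetics-package.R'
    'mutagenesis.R'
    'poisson-core.R'
    'simulate.R'
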