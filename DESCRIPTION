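Package: HiCflux
Title: Time-Resolved Hi-C Analysis of Chromatin Reorganization After
    Condensate Disruption
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of multi-timepoint Hi-C experiments that probe the
    contribution of biomolecular condensates to three-dimensional genome
    folding, for example by transient 1,6-hexanediol treatment. Provides
    contact-matrix depth normalization by downsampling, iterative (ICE)
    balancing and observed-over-expected transforms; distance-decay
    statistics (relative contact probability curves, fold changes, changed
    interaction fractions); A/B compartment calling from the leading
    eigenvector of the contact correlation matrix with TAD-level smoothing,
    per-bin compartment strength, saddle aggregation, interaction
    homogeneity and a multi-timepoint compartment-switch classifier;
    TopDom-style TAD calling with replicate-aware differential boundary
    testing and fusion/shift/separation classification plus aggregate TAD
    analysis; hypergeometric calling of significant TAD-pair interactions
    with condensate-enriched/absent/random classification and aggregate
    peak analysis; signal-track enrichment statistics; and the imaging
    statistics used alongside (Ripley's K and L functions, mean squared
    displacement and diffusion-coefficient fits). A synthetic-data
    generator with planted ground truth (distance decay, compartment
    profile, TAD blocks, loop anchors, perturbation schedules) makes every
    stage verifiable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: HiC, Epigenetics, Software, StatisticalMethod
RoxygenNote: 7.3.3
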