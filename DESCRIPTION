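Package: chipshift
Title: Differential ChIP-Seq Occupancy Classification and Expression Integration
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An integrative pipeline for studying condition-dependent shifts in
    chromatin occupancy, modelled on knockdown experiments of BAF (SWI/SNF)
    chromatin-remodeller subunits in embryonic stem cells. Provides a generic
    window/gap island peak caller with Poisson enrichment against a control
    track, condition-swapped differential peak calling with COMMON / INCREASE /
    DECREASE classification, strand-aware peak-to-gene and enhancer-to-nearest-
    gene annotation, merging of occupancy classes with differential expression,
    a Monte-Carlo permutation test of concurrent binding patterns with a
    Bonferroni-corrected two-sided decision rule and a "highly significant"
    tier, and LOESS-smoothed average binding profiles. A synthetic-data module
    generates a small multi-chromosome genome with planted occupancy classes,
    expression directions and enhancer linkages so that the whole pipeline is
    testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: ChIPSeq, RNASeq, PeakDetection, DifferentialPeakCalling,
    GeneRegulation, Epigenetics, Software
RoxygenNote: 7.3.3
Collate: 
    'chipshift-package.R'
    'AllClasses.R'
    'intervals.R'
    'peaks.R'
    'annotation.R'
    'integration.R'
    'permutation.R'
    'enhancer.R'
    'profiles.R'
    'simulate.R'
    'pipeline.R'
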