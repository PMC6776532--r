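Package: pairHiC
Title: Haplotype-Resolved Hi-C Analysis of Homolog Pairing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies somatic homolog pairing from haplotype-resolved Hi-C
    contact maps. Provides iterative matrix balancing, contact-probability
    scaling curves, pairing-score and cis-score tracks, an aggregated pairing
    score with a bootstrap test for condition differences, two-Gaussian
    deconvolution of the pairing-score distribution into tightly and loosely
    paired bins, boundary-anchored pairing-region classification, diamond
    insulation scores with prominence-based boundary detection, compartment
    eigenvectors, loop quantitation, map-resolution selection and a disomy
    estimator. Includes a synthetic diploid contact-map generator with known
    ground truth so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'binnedGenome.R'
    'contactMap.R'
    'balancing.R'
    'tracks.R'
    'classify.R'
    'compartments.R'
    'insulation.R'
    'pairHiC-package.R'
    'pairing.R'
    'scaling.R'
    'simulate.R'
    'pipeline.R'
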