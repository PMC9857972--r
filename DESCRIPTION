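Package: hicstruct
Title: Consensus 3D Genome Structure Inference from Hi-C Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers a consensus three-dimensional model of chromatin from
    Hi-C contact-count matrices by maximum likelihood under a negative
    binomial observation model. Contact counts between two genomic loci are
    modeled with a mean that decays as a power law of the Euclidean distance
    between the corresponding beads and a separate dispersion parameter that
    captures the overdispersion characteristic of Hi-C data. The package
    provides ICE matrix balancing, a distance-stratified estimator of the
    global dispersion, gradient-based multi-restart L-BFGS optimization of
    bead coordinates jointly with the count-to-distance exponent, a Poisson
    baseline, a synthetic Hi-C simulator with tunable coverage, dispersion
    and decay exponent, and evaluation utilities (superposition RMSD,
    distance-matrix Spearman correlation, nucleus rescaling, resolution
    coarsening, binomial downsampling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    generics,
    ggplot2,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
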