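Package: mesofiber
Title: Nucleosome-Resolution Mesoscale Chromatin Fiber Modelling and Monte
    Carlo Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, samples and analyzes coarse-grained chromatin fibers at
    nucleosome resolution. Nucleosome cores are rigid bodies carrying discrete
    Debye-Hueckel surface charges, linker DNA is a wormlike bead chain with
    stretching, bending and twist-deviation penalties, histone tails and linker
    histones are flexible charged bead chains, and fibers can carry the
    macroH2A1 histone variant (canonical, variant or hybrid cores), histone
    tail acetylation, nucleosome-free regions, harmonic genomic-loop restraints
    and CAG-repeat linker expansions. Equilibrium ensembles are generated with
    Metropolis Monte Carlo (pivot, local, configurational-bias tail regrowth,
    linker-histone and tail swap-fold moves) over independent replicas, and
    analyzed for packing ratio, sedimentation coefficient, radius of gyration,
    internucleosome contact maps and their one-dimensional decomposition,
    nucleosome clutches, fiber persistence length, local geometry, tail
    interaction profiles and epigenetic contact classes. Includes a synthetic
    input generator (nucleosome position tracks, charge profiles, ready-made
    fiber recipes) so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml,
    bio3d,
    rtracklayer,
    GenomicRanges,
    IRanges
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
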