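Package: dwtmotif
Title: Dinucleotide Weight Tensor Models for Transcription Factor Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Regulatory motif models that incorporate arbitrary pairwise
    dependencies between binding-site positions. The dinucleotide weight
    tensor (DWT) is a Bayesian network motif model that marginalizes
    analytically over all spanning-tree factorizations of the joint
    distribution of letters at pairs of positions, using Dirichlet-marginal
    likelihoods and the generalized matrix-tree theorem. The package
    provides motif inference by expectation maximization from sets of bound
    sequences (ChIP-seq peaks), binding-energy scoring of sequences under
    PSWM, adjacent-dependency (ADJ), and full DWT models, likelihood
    evaluation on HT-SELEX selection rounds with a fitted selection
    temperature, decoy-based precision-recall benchmarking, seed-exact
    synthetic data generators, and 'dilogo' motif visualization as SVG.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
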