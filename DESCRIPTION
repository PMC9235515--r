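Package: marginalign
Title: Reliability of Pairwise Protein Sequence Alignments via Marginalized
    Alignment Distances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how trustworthy a pairwise protein sequence alignment is.
    Implements minimum message length (MML) optimal and marginalized sequence
    comparison under time-parameterized Markov substitution models with automatic
    inference of the divergence (Markov time) parameter, a skew-diagonal distance
    between alignment paths, an exact quadratic-time dynamic program for the
    posterior-weighted expected distance of all alignments of a pair to a fixed
    reference (structure) alignment, stochastic traceback sampling of alignments
    from the marginal probability matrices, daylight/twilight/midnight divergence
    zone classification, and a synthetic generator that evolves sequence pairs at
    a known Markov time with a known true alignment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
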