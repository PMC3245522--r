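Package: chromconf
Title: Chromatin Conformation Ensembles from 5C and Hi-C Data by MCMC
    Sampling
Version: 0.1.0
Authors@R:
    person("Chromconf", "Developers", email = "chromconf@example.org",
           role = c("aut", "cre"))
Description: Infers ensembles of three-dimensional chromatin conformations
    from chromosome conformation capture (5C and Hi-C) interaction
    frequency data. A power-law model links pairwise interaction
    frequencies to Euclidean distances between restriction sites; a
    Gaussian observation model (per-pair standard deviations for 5C, a
    normal approximation to multinomial read counts for Hi-C) defines a
    posterior over conformations that is sampled by Metropolis-Hastings
    with single-point spherical proposals and a two-chain mixing
    diagnostic. Includes rotation/reflection-invariant ensemble
    clustering (Ward and k-means), greedy reliable-substructure
    detection, base-resolution structural properties (density,
    compaction, looping), leave-one-out cross-validation for the
    distance exponent, physical-scale calibration, a synthetic data
    generator for validation, PDB export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
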