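Package: mtfold
Type: Package
Title: Magnetic-Tweezers Analysis of Two-State Protein Folding Under Force
Version: 0.1.0
Authors@R: person("mtfold", "developers", email = "mtfold@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis tools for single-molecule magnetic-tweezers
    force spectroscopy of two-state protein folding. Provides Gillespie
    simulation of folding/unfolding bead-height trajectories under
    constant-force, force-ramp and force-jump protocols; worm-like-chain and
    freely-jointed-chain elasticity models and force-dependent unfolding step
    sizes; Bell-model force-dependent rate laws and the Evans-Ritchie
    rupture-force distribution at constant loading rate, with
    maximum-likelihood and histogram fitting; two-state hidden-Markov
    segmentation of noisy trajectories with dwell-time extraction and
    exponential survival analysis; and reconstruction of the zero-force
    free-energy landscape (native state, two sequential transition states,
    unfolded reference) along the N-to-C terminal distance coordinate.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
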