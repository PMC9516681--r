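Package: memperm
Title: Membrane Permeability of Cyclic Peptides from Biased Sampling
    Along the Membrane Normal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates passive membrane permeability of cyclic peptides
    from umbrella-sampling data along the membrane-normal coordinate z.
    Provides a weighted histogram analysis method (WHAM) solver for 1D
    potentials of mean force with half-split uncertainty and 2D
    bias-reweighted surfaces, position-dependent diffusion coefficients
    from the autocorrelation of restrained trajectories, and a modified
    inhomogeneous solubility-diffusion model with flip/out endpoint rules.
    A self-contained overdamped Langevin / replica-exchange umbrella
    sampling generator produces membrane-like test data, and
    conformational observables (hydrogen bonds, polar surface area,
    dihedral principal components, cis peptide bonds, inertia axes) can
    be profiled along z.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
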