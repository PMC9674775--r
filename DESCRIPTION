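Package: firstpassage
Title: First-Passage-Time Distributions of Diffusions with Moving Boundaries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes first-passage-time (decision-time) probabilities of
    one-dimensional diffusions with time-dependent absorbing boundaries and
    space-time-dependent drift, as used in diffusion decision models of
    response times. The backward Fokker-Planck problem is mapped to the unit
    square by a time warp and an affine space map, the corner singularity
    between initial and boundary data is removed by subtracting a
    constant-drift reference solution evaluated from rapidly converging
    series, and the smooth remainder is solved with a space-time
    minimal-residual Petrov-Galerkin finite element method. The dependence on
    model parameters is emulated with Smolyak sparse-grid interpolation on
    nested Clenshaw-Curtis nodes. A seeded Euler-Maruyama simulator with
    Brownian-bridge crossing corrections provides an independent Monte-Carlo
    reference.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
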