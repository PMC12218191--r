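Package: netecon
Title: Economical Representation and Growth of Spatial Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the economical representation of spatial (geometric)
    networks. Implements optimal graph filtering by maximizing a benefit-cost
    functional J = rho^alpha (1 - delta)^beta that trades connection density
    against cumulative edge length, with closed-form optima for short-range,
    random and long-range weight-length regimes and size scaling
    alpha = phi N^(-1/s); exact edge-crossing counting with the quadratic
    density scaling law Ec = Ec_max rho^2; a benefit-cost spatial growth model
    with uniform- and preferential-attachment special cases and an accelerated
    hidden-variable variant; a two-step calibration pipeline (edge-count grid
    search followed by particle-swarm refinement of Jensen-Shannon
    divergences); and utilities for jittered-grid perception-experiment
    layouts, Gamma-Poisson (negative binomial) overdispersed count fits and
    effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    MASS,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
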