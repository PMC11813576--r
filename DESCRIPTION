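Package: kmcapture
Title: Kinetic Monte Carlo Simulation of Diffusive Capture in Exterior Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact-propagator kinetic Monte Carlo simulation of Brownian
    particles captured by absorbing sites on a reflecting plane bounding a
    half-space, or on the surface of a convex polyhedron in an exterior
    domain.  Trajectories are advanced by three analytically solvable
    projection steps (first passage to a plane, exit from a hemisphere, and
    arrival on or escape past an enclosing sphere), so arrival times are
    sampled without time-stepping error.  The package also provides the
    matched-asymptotic flux expansions for well-separated circular pores on
    the plane, boundary-homogenized (Robin) arrival-time distributions for
    patchy spheres, exterior-sphere splitting probabilities, and estimators
    (capacitance, log-binned arrival histograms, empirical cumulative
    fluxes, ratiometric differential flux) used to validate simulations
    against the theory.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
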