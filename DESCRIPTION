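Package: delaybasin
Title: Basin Stability for Delay Differential Equations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generalized basin stability for dynamical systems with discrete
    time delays. The infinite-dimensional space of initial history functions
    is projected onto a finite coefficient hypercube by expansion in a
    trigonometric, Legendre or Bernstein basis; the volume of an attractor's
    basin is then estimated by Monte-Carlo sampling of the hypercube, with
    convergence scans in the expansion order and coefficient bound and a
    cross-validation procedure over the three bases. Includes a fixed-step
    method-of-steps integrator for delay differential equations, a
    multistable delayed Hopfield neuronal model, and master-stability-function
    tools for synchronization of delay-coupled oscillator networks
    (Watts-Strogatz topologies, transverse Lyapunov exponents, mean basin
    stability of the synchronization manifold).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    igraph,
    pracma,
    jsonlite,
    yaml,
    generics,
    rlang,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
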