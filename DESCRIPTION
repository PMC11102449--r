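Package: hypadsim
Title: Hybrid Agent-Based Simulation of Hypoxia- and Adenosine-Mediated
    Tumor Escape in Dendritic-Cell Immunotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A spatio-temporal hybrid model of tumor-immune dynamics under
    dendritic-cell (DC) based immunotherapy. Tumor and immune cells live on a
    two-dimensional lattice with Moore neighborhoods: tumor cells divide only
    at the rim, inactive immune cells perform Levy walks while activated cells
    move by Brownian motion, effector cells kill adjacent tumor cells serially
    and regulatory T cells deactivate DCs. Oxygen diffuses from boundary
    vessels through a block-discretized reaction-diffusion scheme; hypoxia
    (the inverse of local oxygen) drives a global adenosine pool which, with
    hypoxia itself, modulates tumor proliferation, Treg polarization and
    effector cytotoxicity. Hypoxia- and adenosine-inhibitor vaccines follow
    bolus-decay pharmacokinetics with an adhesion moving-average filter.
    Includes the eight experimental treatment groups and dose/timing protocol
    variants, replicate aggregation with confidence intervals, goodness-of-fit,
    Latin-hypercube/PRCC global sensitivity analysis and pairwise
    identifiability screening. The stepping engine is implemented in C++ via
    Rcpp.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lhs,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
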