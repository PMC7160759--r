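Package: dendrogen
Title: Generation of Dendritic Morphologies from a Spatially
    Heterogeneous Branching-Rate Estimate
Version: 0.1.0
Authors@R: person("Morphology", "Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates the spatial heterogeneity of dendritic branching from
    SWC-format neuronal reconstructions using a state-space point-process
    filter, fixed-interval smoother and expectation-maximization, then grows
    new morphologies by thinned inhomogeneous point processes with
    conditional branch-angle sampling and anatomical-boundary termination.
    Includes morphometric comparison tools (Sholl analysis, dendritic-length
    profiles, distribution RMSE) and a passive resistor-network model of
    proximal current flow for validating generated populations against
    reference reconstructions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
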