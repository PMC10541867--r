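Package: planktonpatch
Title: Lagrangian Moment-Closure Simulation of Plankton Patch Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a planktonic ecosystem drifting inside an elliptical
    Lagrangian water patch that is stretched by horizontal strain and diluted
    by eddy diffusion. The patch carries an inorganic resource (iron) and a
    phytoplankton consumer whose spatial means, variances and covariance
    evolve under entrainment of surrounding water, internal mixing, and
    moment-closed Monod growth with linear (or quadratic) mortality. Includes
    a preset reproducing the SOIREE iron-fertilization bloom, strain-by-
    diffusion ensemble runs contrasting well-mixed and heterogeneous patches,
    and diagnostics such as the Lagrangian biomass anomaly (LBA), dilution
    factor and heterogeneity contribution to growth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
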