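Package: leafcp
Title: Leaf Specific Heat Capacity from Thermal Transients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the specific heat capacity of leaves (and reference
    materials such as painted aluminum plates) from thermography time series.
    A dynamic leaf energy-balance model describes the temperature transient of
    a sample exposed to a short light pulse; Bayesian inversion of the
    transient recovers the areal heat capacity k together with boundary-layer
    and stomatal conductances, and specific heat capacity follows as k divided
    by the fresh mass per unit area. Includes a forward simulator with
    synthetic-data generation, psychrometric and flux helpers, leaf-trait
    calculators (water content, specific leaf area, leaf mass per area,
    reference-emittance emissivity), a one-at-a-time input sensitivity
    analysis, CSV/JSON readers and writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
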