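Package: surfkin
Title: Kinetic Modelling of Fed-Batch Surfactin Production by Bacillus subtilis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, calibration and model-based design of exponential-feed
    fed-batch bioreactor processes for surfactin production by Bacillus
    subtilis. Implements a four-state ordinary differential equation model
    (biomass, glucose, surfactin, acetate) with Monod growth kinetics,
    acetate inhibition, threshold-switched overflow metabolism, Pirt
    maintenance, growth-coupled product formation and reactor/feed volume
    dynamics. Provides event-driven integration over batch and feeding
    phases, RMSE-based bounded parameter estimation, Morris elementary-effects
    sensitivity screening, carbon mass-balance validation, initial-feed-rate
    design sweeps, and a synthetic-data generator emulating duplicate
    fed-batch experiments across a range of feeding growth rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
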