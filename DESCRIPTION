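Package: wpiocc
Title: Dynamic Occupancy Models and the Wildlife Picture Index for
    Camera-Trap Community Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for monitoring terrestrial vertebrate communities from
    camera-trap deployments. Builds daily and period-collapsed detection
    histories from event and deployment tables, fits multi-season (dynamic)
    occupancy models with imperfect detection by marginalized maximum
    likelihood and by a self-contained Gibbs/Metropolis sampler, checks fit
    with chi-square Bayesian posterior predictive checks, and derives
    community indicators from the posterior draws: the Wildlife Picture
    Index (geometric mean of baseline-relative occupancies), lambda-ratio
    occupancy change classification, and detection-corrected species
    richness scaled to a regional pool. A synthetic-community generator
    with known truth supports calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
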