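Package: coopdyn
Title: Individual-Based Simulation of Cooperation, Resources, and
    Population Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An individual-based model of group-structured populations of
    cooperators and free-riders in which environmental resource
    availability, an evolving cooperation trait, and population size feed
    back on one another.  Cooperators generate shared group resources
    through a saturating (Monod-type) benefit function at a personal
    reproductive cost; reproduction saturates with per-capita resource
    intake and survival declines exponentially with age.  Includes
    constant and sinusoidally forced environments, replicate aggregation,
    time-lagged cross-correlation between environmental forcing and
    population size, amplitude spectra of mean-standardized population
    fluctuations, experiment presets and sweeps, and a parameter
    calibration smoke test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
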