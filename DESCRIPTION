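Package: mjmove
Title: Habitat-Specific Butterfly Movement Analysis and Individual-Based Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing habitat-specific movement and activity of
    grassland butterflies (developed around field protocols for the meadow
    brown, Maniola jurtina) and for forecasting dispersal with an
    individual-based model. Provides a synthetic field-observation generator
    (flag-based tracks and behaviour logs), the five standard movement
    statistics (step speed, turning angle, flight duration, inter-flight
    duration, net displacement) and behavioural time budgets, empirical-CDF
    inverse-transform samplers, duration-conditioned step-length sampling, von
    Mises turning-angle fits, neutral fractal landscapes (midpoint
    displacement, Hurst parameter), an event-driven correlated random walk
    with explicit activity budgets under four parameterization variants, and
    dispersal-kernel summaries (mean displacement, Pearson kurtosis,
    large-sample kurtosis confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
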