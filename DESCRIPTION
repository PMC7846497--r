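Package: lvattention
Title: Nonautonomous Lotka-Volterra Analysis of Search-Attention Time Series
Version: 0.1.0
Authors@R:
    person("Attention", "Dynamics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers time-varying competitive interactions among topics from
    relative search-interest time series (Google-Trends-style 0-100 panels).
    Topic attention is modelled as market shares of a logit discrete-choice
    system with an outside search option; latent utility functions are
    recovered as log-odds, smoothed with a Fourier-series (or polynomial)
    least-squares fit, and differentiated analytically to obtain the
    interaction coefficients of an integrable nonautonomous Lotka-Volterra
    system. Sign patterns of the coefficients classify pairwise ecological
    roles (competition, predator-prey, mutualism, commensalism, amensalism,
    neutralism), and the summed absolute coefficients give an interaction
    intensity curve with a changepoint detector for regime shifts. A
    synthetic-data generator with known ground truth makes the full pipeline
    testable without any live data source.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
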