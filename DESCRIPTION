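Package: plumecoding
Title: Efficient Coding of Turbulent Odor-Plume Timescales by Olfactory
    Receptor Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how olfactory receptor neurons encode the
    temporal statistics of turbulent pheromone plumes. Simulates whiff/blank
    stimulus sequences with truncated power-law duration statistics at virtual
    distances from an odor source, generates synthetic spike-train recordings
    from parametric encoding models, estimates response latency
    nonparametrically from paired spike/onset intervals, fits duration-rate
    encoding models (cubic smoothing spline mean, robust IQR-based variance
    smoothed by tricube-weighted local linear regression), and derives Fisher
    information coding-accuracy profiles, average decoding accuracy under
    matched and mismatched plume statistics, and the Jeffreys-prior optimal
    stimulus distribution with quantile-quantile comparison against the true
    blank-duration distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
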