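Package: sinkeff
Title: Trends and Trend Reversals in Land Carbon Sink Efficiency
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to compute the instantaneous land carbon sink efficiency
    E = B/(F + L) from harmonized regional annual carbon-flux series, detect
    decadal trend reversals with one-breakpoint segmented regression
    (bootstrap significance and confidence intervals), attribute a global
    breakpoint to regions with leave-one-out and leave-two-out slope-change
    ratios, and propagate flux uncertainties to E by Monte Carlo. Includes a
    synthetic multi-dataset flux-panel generator with known truth (trends, a
    post-2009 tropical sink reversal, a Pinatubo-like 1991-1993 pulse,
    AR(1) and ENSO-like variability, and climate covariates) so the full
    pipeline is testable without external inversion or budget products.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
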