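Package: fisherinfo
Title: Fisher Information Stability Index for Multivariate Time Series
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the discrete Fisher information stability index for
    multivariate time series and uses it to track regimes and detect regime
    shifts. Observations are binned into discrete system states by a greedy
    hyper-rectangle procedure whose per-variable bin widths (the "size of
    state") can be estimated from a stable reference period via Chebyshev's
    inequality. Fisher information is evaluated over a sliding window from
    the square-root amplitudes of the state probabilities, with optional
    tightening-level averaging for noisy data, block-average smoothing, and
    per-period regime summaries (mean and standard deviation of the index).
    Includes a reader for GISTEMP-style monthly temperature-anomaly tables,
    a seeded generator of piecewise-stationary regime-shift test series, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
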