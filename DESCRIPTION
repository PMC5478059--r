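Package: neutralmig
Title: Migration Estimation for Spatially Implicit and Semi-Explicit
    Neutral Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for simulating local tree communities under zero-sum
    neutral dynamics and estimating the migration (immigration) parameter
    m with several estimator families from community ecology and
    population genetics: a Gst-style differentiation statistic,
    Dirichlet-multinomial ("Inference") likelihood, Etienne's one-stage
    and two-stage sampling formulas, and a plot-geometry method based on
    dispersal kernels. Includes Fisher's logseries metacommunity
    construction, a spatially implicit Hubbell-type local community
    simulator, a spatially semi-explicit lattice simulator with
    recruitment from adjacent plots and the metacommunity, and pipelines
    for parameter-recovery, additivity and field-emulation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
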