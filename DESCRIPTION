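Package: hdmks
Title: Homotopy Decomposition Series Solutions for the One-Dimensional
    Keller-Segel Chemotaxis System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Symbolic series solver for the one-dimensional Keller-Segel
    chemotaxis system using the homotopy decomposition method (HDM).
    Builds series terms order by order from an Abel-kernel inverse time
    operator and He-polynomial decompositions of the chemotactic
    nonlinearity, for constant, linear and quadratic sensitivity
    functions.  Includes a small exact symbolic kernel closed under the
    operations the recursion needs, a printed-term fixture library for
    the three worked examples with known-discrepancy reporting, numeric
    evaluation of truncated series with divergence diagnostics, the
    closed-form limit check for exponential initial data, and an
    independent method-of-lines finite-difference reference solver with
    zero-flux Neumann boundaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
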