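Package: hopnet
Title: Minimal Connectivity of Attractor-Supporting Hopfield Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how much connectivity a Hopfield-type
    threshold network needs to support its attractors. Builds fully
    connected +/-1 networks with a single designated attractor from the
    Hebbian outer-product rule, iterates them synchronously with fixed-point
    and short limit-cycle detection, prunes links one at a time down to a
    minimal configuration that still funnels every random initial state to
    the designated attractor, grafts a second orthogonal attractor onto the
    minimal skeleton and prunes again while tracking when the second
    attractor is lost. Includes exhaustive small-network attractor
    enumeration as an oracle, degree-distribution and convergence-speed
    summaries with ln(N) scaling, and seeded, fully reproducible experiment
    runners with plain-text outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
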