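Package: kinoed
Title: Optimal Experimental Design for Enzyme Inhibition Kinetics under
    Additive and Multiplicative Error
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for designing and analysing enzyme inhibition experiments
    based on Michaelis-Menten type rate laws (competitive, non-competitive and
    a four-parameter encompassing model), on both the original rate scale with
    additive normal errors and the log-transformed scale with multiplicative
    log-normal errors.  Provides nonlinear least-squares estimation with
    standard, log and back-transformed residual summaries, locally D- and
    Ds-optimal designs for parameter estimation (multiplicative weight /
    vertex-exchange algorithms with equivalence-theorem certification), T-,
    compound-T- and delta-optimal discriminating designs (Fedorov-Wynn and
    KL-exchange algorithms with bounded-variable least squares), efficient
    rounding of approximate designs to exact ones, Monte-Carlo evaluation of
    discriminatory power (hit rates), a synthetic substrate-inhibitor plate
    generator, and IC50 / percent-inhibition arithmetic for well-plate layouts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
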