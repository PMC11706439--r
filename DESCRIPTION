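Package: baroloop
Title: Closed-Loop Baroreflex-Regulated Cardiovascular Models and Their
    Sensitivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pulsatile one-chamber and four-chamber lumped-parameter (0D)
    cardiovascular models closed-loop coupled to an Ursino-style baroreflex
    (afferent transduction, sympathetic and vagal efferent arcs with
    transport delays, beat-to-beat regulation of heart period and
    contractility, continuous regulation of systemic resistance and venous
    unstressed volume), formulated as a smooth delay-differential system
    and integrated with a compiled fixed-step solver. Includes the
    regulated-to-unregulated equivalence protocol, scaled local sensitivity
    matrices, and variance-based Sobol global sensitivity analysis with
    Saltelli/Jansen estimators, bootstrap confidence intervals, convergence
    traces and error summaries.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    rlang,
    generics,
    lhs,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
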