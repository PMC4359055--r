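Package: hscdynamics
Title: Division Kinetics and Homeostasis Modelling of Hematopoietic Stem Cell Subsets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to quantify how long human hematopoietic stem cells (HSCs)
    take to leave quiescence and divide, and to explore the consequences of
    that latency for stem-cell pool homeostasis. The package generates
    synthetic single-cell division-tracking experiments, fits log-logistic
    sigmoids to cumulative division curves to estimate times to first and
    second division (and hence the duration of G0 exit), fits saturating
    BrdU label-incorporation curves to estimate population doubling times,
    estimates repopulating-cell frequencies from limiting-dilution
    transplantation tables under a single-hit Poisson model, and simulates
    an agent-based model of long-term HSC, short-term HSC and progenitor
    compartments under closed-loop demand control, comparing one-parameter
    and two-parameter control of cell division with an optional delay in
    LT-HSC quiescence exit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
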