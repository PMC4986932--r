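Package: ihtrace
Title: Identification of Fast and Slow Ih Current Components from
    Voltage-Clamp Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying the parameters of hyperpolarization-
    activated cation (Ih) currents composed of a fast and a slow HCN
    component from whole-cell voltage-clamp trace sets. Implements the
    classical per-trace ("single-trace") identification baseline and a
    simultaneous all-trace ("full-trace") nonlinear least-squares method
    with multi-start initialization and best-mode trial selection, a
    synthetic voltage-clamp generator for benchmarking both methods,
    per-parameter error reports and sensitivity sweeps, and a conductance-
    based sustained/transient vestibular ganglion neuron model carrying
    the identified Ih components, with EPSC, conditioning and rebound
    stimulation protocols and cAMP modulation of the HCN gates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
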