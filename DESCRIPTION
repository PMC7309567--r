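Package: olmivl
Title: In Vivo-Like States and Ionic Current Contributions in
    Multi-Compartment Interneuron Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Conductance-based multi-compartment simulation of hippocampal
    OLM (oriens lacunosum-moleculare) interneurons under quiescent in-vitro
    and synaptically bombarded in vivo-like (IVL) conditions.  Provides a
    Crank-Nicolson cable solver with Hodgkin-Huxley-style channel mechanisms,
    dual-exponential synapses with incremental weight fitting against target
    postsynaptic current amplitudes, Poisson bombardment ensembles with
    common-input grouping, an IVL-state metric with a ten-seed consistency
    rule, and analysis tools for per-channel current decomposition
    (currentscape), total transferred charge, and normalized
    cross-correlation timing of ionic currents across somatic and dendritic
    recording sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
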