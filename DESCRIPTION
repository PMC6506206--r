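Package: tcsynapse
Title: Dynamics of Thalamocortical Synaptic Transmission from Paired In
    Vivo Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize monosynaptic transmission between
    thalamic (LGN) relay cells and cortical (V1) neurons recorded in vivo.
    Detects connected cell pairs by jitter-corrected spike-triggered
    averaging of membrane potential with bootstrap confidence bands,
    labels every presynaptic spike as a detectable or undetectable EPSP
    with an automated amplitude-and-latency detector, and summarizes
    synaptic reliability, noise-corrected amplitude variability and
    short-term plasticity per connection and across populations. Includes
    a conductance-based leaky integrate-and-fire model of a layer-4
    simple cell driven by tens of geniculate inputs, used to compare
    reliable against unreliable/variable synapses, and a synthetic-data
    generator (white-noise stimulus, linear-nonlinear-Poisson LGN spike
    trains, ground-truth-labeled membrane-potential traces) so that the
    whole pipeline is testable without experimental recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
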