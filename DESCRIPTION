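Package: tremorRN
Title: Recurrence-Network Analysis of Subthalamic Local Field Potentials
    for Demand-Driven Deep Brain Stimulation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nonlinear dynamical analysis of subthalamic-nucleus local field
    potentials (LFPs) for closed-loop, demand-driven deep brain stimulation.
    Implements moving-window epsilon-recurrence-network analysis of
    delay-embedded LFP windows (delay from the first local minimum of the
    auto-mutual information, dimension from false nearest neighbours, link
    threshold fixed by recurrence rate), global network measures (clustering,
    transitivity, degree assortativity) with moving-median significance bands,
    an EMG-grounded tremor-onset labeller, a peak-triggered start / SVM-stop
    stimulation controller with cross-validated validity reporting, and a
    synthetic generator of labelled LFP+EMG recordings with a controlled
    nonlinearity transition for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
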