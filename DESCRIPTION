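Package: clocknets
Title: Delay-Coupled Spiking Columns and Generalised Kuramoto Clock Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and reverse-engineering cortex-like
    network-of-networks dynamics. Generates densely connected neural-column
    graphs with real-valued transmission delays and range-dependent
    column-to-column grids; runs exact event-driven simulations of
    excitable-refractory (leaky integrate-and-fire) neurons and of
    generalised Kuramoto networks of k-dimensional clocks coupled by
    delayed phase-resetting maps; estimates the number of dynamical
    degrees of freedom k from recordings via delay embedding and the
    Grassberger-Procaccia correlation dimension; and discovers
    hierarchical dynamical response "modes" from batteries of stimulation
    experiments, with permutation significance, mode-competition and
    preconditioning measures. Includes the unit-delay quenching
    experiment, in which replacing heterogeneous real-valued delays by a
    single unit delay collapses arrival-time diversity and the attained k.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
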