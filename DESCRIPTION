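Package: linkbal
Title: Forward-Time Simulation of Linked Balanced Polymorphisms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Wright-Fisher forward-time simulation of two linked diallelic
    loci, each under symmetric balancing selection (overdominance) with no
    epistasis between them. Tracks the four gamete haplotypes under
    selection, recombination and multinomial drift, records per-replicate
    fixation times and retained-haplotype outcomes, and aggregates them into
    retention proportions, censored median times to fixation, and log-log
    regressions of fixation time and retention count on the
    population-scaled recombination rate. Includes an additive and a
    multiplicative (large-dominance approximation) fitness scheme, an exact
    Markov-chain absorption oracle for tiny populations used to validate the
    simulator, and a grid runner for parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
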