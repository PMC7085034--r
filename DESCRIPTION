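Package: anklewc
Title: Worst-Case Uncertainty Analysis of a Planar Ankle Joint Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Static planar model of a ligamentous joint (the ankle) built
    from tension-only exponential cables and a conforming Hertzian
    sphere-sphere contact pair, solved for equilibrium over a schedule of
    external moments with a Levenberg-Marquardt least-squares solver.
    Implements an adversarial worst-case uncertainty analysis: two complete
    43-parameter model variants are co-encoded in one 86-element decision
    vector and co-optimised with a real-coded genetic algorithm (roulette
    selection, blx-alpha crossover, non-uniform mutation, elitism) to
    maximise the weighted L1 distance between their moment-rotation curves,
    alongside a one-at-a-time sensitivity baseline and the associated
    summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
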