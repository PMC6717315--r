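Package: nucdomains
Title: Chromatin Interaction Domains from Nucleosome Positions via
    Polymer Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts nucleosome-resolution chromatin interaction maps and
    domain boundaries in budding yeast from one-dimensional nucleosome
    positions alone.  A chromatin fiber is modelled as a bead-spring
    heteropolymer (2.5-nm DNA beads, 10-nm nucleosome spheres, 50-nm DNA
    persistence length, excluded volume only), sampled by Langevin
    dynamics, and observed through a stochastic cross-linking model with a
    tunable cross-linker length scale to produce simulated MicroC contact
    maps.  Includes insulation-score boundary calling with Monte-Carlo
    null p-values, contact-probability P(s) power-law fits, radius-of-
    gyration analytics, linker-length context statistics, and a synthetic
    generator for multimodal nucleosome spacing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    S4Vectors,
    BiocGenerics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
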