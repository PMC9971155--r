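Package: dyadnet
Title: Dyadic Association Networks from Focal-Sampling Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing inter- and intrasexual social bonding from
    focal-sampling observation records, as used in primate social network
    studies. Converts focal samples into daily-binarized association streams,
    computes simple-ratio association indices for party co-residence,
    direct (1 m) proximity and grooming, fits hurdle beta/binomial mixed
    models with crossed individual random intercepts (Laplace approximation
    with a compiled likelihood), tests group-by-dyad-sex interactions with datastream
    (prenetwork) permutations, and draws sociograms with force-directed
    layouts and spinglass communities. Includes a synthetic-data generator
    that emulates the focal-sampling observation process so every stage of
    the pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmmTMB,
    emmeans,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
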