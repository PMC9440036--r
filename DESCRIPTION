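Package: bdmsao
Title: Hybrid Binary Dwarf Mongoose - Simulated Annealing Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper-based feature selection for high-dimensional classification
    data (e.g. microarray gene-expression profiles) using a binary Dwarf
    Mongoose Optimization (BDMO) population search hybridized with a simulated
    annealing (SA) local-search stage and a k-nearest-neighbour wrapper
    fitness. Provides dataset readers (CSV, ARFF), stratified
    cross-validation, the binary DMO search operators (alpha foraging,
    sleeping-mound bookkeeping, scouting, babysitter exchange), bit-flip
    simulated annealing with Metropolis acceptance, synthetic planted-feature
    data generators with an exhaustive subset oracle, and rank-based
    benchmarking utilities (Friedman mean ranks, Wilcoxon signed-rank).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    foreign,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    caret,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
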