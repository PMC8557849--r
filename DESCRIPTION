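Package: moranlink
Title: Linked-Site Amino Acid Substitution via k-Allele Moran Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Models amino acid substitution on a phylogenetic branch when
    sites are completely linked (no recombination).  Provides the k-allele
    continuous-time Moran process (state-space enumeration, sparse
    generators, transient/absorbing partition), exact and approximate
    fixation quantities for the two-allele process (long-run fixation
    probability by sparse linear solve, conditional fixation-time moments,
    a Gumbel-mixture finite-time approximation), the probability that two
    or more substitutions on a branch fixed together versus sequentially
    (fixation histories), exact Gillespie simulators for the finite-sites
    and tracked infinite-sites models, and a branch likelihood for relative
    fitnesses given an observed substitution history.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    stats,
    utils,
    pracma,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
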