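Package: cnphylo
Title: Maximum Likelihood Phylogenies from Tumour Copy-Number Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Maximum likelihood inference of a single patient's sample
    phylogeny, node ages and per-year duplication/deletion rates from total
    or haplotype-specific integer copy-number profiles, such as those called
    from shallow whole-genome sequencing. Copy-number evolution is modelled
    as a continuous-time Markov chain on haplotype-specific states with an
    absorbing zero-copy state; total copy numbers are handled as ambiguous
    observations via Felsenstein pruning. Supports time-calibrated dating of
    longitudinal samples, exhaustive and heuristic (stepwise addition plus
    NNI) topology search, marginal and joint ancestral reconstruction,
    bootstrap branch support and confidence intervals, and a companion
    simulator of copy-number evolution along coalescent sample trees,
    including multi-scale events, calling errors, subclonal mixtures and
    relative copy-number output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    pracma,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
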