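Package: swnull
Title: Null-Model Benchmarking of Small-World Parameters in Structural
    Correlation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds gray-matter-style structural correlation networks from
    subject-by-region morphometry tables, generates three families of null
    networks (connected degree-preserving topology randomization, random
    covariance matrices moment-matched by the Hirschberger-Qi-Steuer
    construction, and subject-wise data permutation), computes normalized
    small-world parameters over density grids, and tests within-group and
    between-group differences with a functional-data-analysis area statistic
    under bootstrap and permutation resampling. Includes a synthetic
    two-group morphometry generator with block-structured correlation so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    jsonlite,
    car,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
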