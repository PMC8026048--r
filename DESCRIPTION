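Package: spacerlaw
Title: Heavy-Tailed Distributions and Markov-Chain Dynamics of CRISPR Spacer Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the distribution of spacer counts across
    CRISPR arrays in metagenomes and prokaryotic genomes. Provides discrete
    heavy-tailed probability families (truncated power law, power law,
    exponential, stretched exponential, lognormal) with maximum-likelihood
    fitting, Vuong-style loglikelihood-ratio model selection, a discrete-time
    Markov-chain model of spacer gain and loss under phage pressure with
    stationary-distribution solvers, a synthetic spacer-count data generator,
    and tidy pipeline wrappers with ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
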