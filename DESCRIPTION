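Package: coevoscan
Title: Detecting Coevolving Host-Parasite Loci from Interspecific
    Allele-Frequency Correlations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens pairs of host and parasite loci for spatial
    correlations in allele frequencies across populations, the genomic
    signature of locally adapted coevolution. Provides the correlation
    scan with t-based significance calls, the local-adaptation statistic
    computed from reciprocal cross-infection matrices together with its
    genotype-covariance decomposition, an individual-based forward
    simulator of haploid host-parasite coevolution in a linear
    stepping-stone metapopulation (discrete-matching and
    quantitative-matching infection models), a replicate harness for
    power and type I error calibration, and a synthetic frequency-table
    generator for testing the scan independently of the simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
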