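Package: karyevo
Title: Chromosome Number and Sex Chromosome System Evolution on Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of haploid chromosome-number evolution and
    sex chromosome system (SCS) turnover on time-calibrated phylogenies.
    Implements a bounded continuous-time Markov model with chromosome fission,
    fusion, polyploidy and optional demiploidy (optionally linked to a binary
    trait such as reproductive mode), Felsenstein pruning likelihoods,
    maximum-likelihood fits and likelihood-ratio tests, Metropolis-Hastings
    MCMC repeated over a posterior sample of trees with burnin, thinning and
    pooling to per-million-year rates, highest-posterior-density intervals and
    clade rate comparisons, marginal ancestral-state reconstruction, stochastic
    character mapping with per-event-type counts, genus-level comparison of
    mean autosome numbers between XO, XY and multi-XY species to classify
    sex-chromosome fusions versus fissions, tip rates of chromosome-number
    change, and ordinary plus phylogenetically corrected regressions of
    chromosome number and tip rates on genome size. Includes generators for
    synthetic posterior tree sets and karyotype tables, tidy() and glance()
    methods, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    Matrix,
    phytools,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
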