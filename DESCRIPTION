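Package: exactperm
Title: Exact and Monte Carlo Permutation Tests for Small-Sample Experimental Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Randomization inference for the small, dependence-prone datasets
    typical of laboratory and field experiments. Implements the full family of
    exact and Monte Carlo permutation tests built from three ingredients: an
    admissible relabeling scheme implied by the experimental design (two-sample
    splits, multi-sample splits, matched-pair sign flips, full orderings, and
    stratified products of any of these), a test statistic computed on raw or
    rank-transformed data (difference in means, one-way F, Kruskal-Wallis H,
    Jonckheere-Terpstra J, a magnitude-sensitive directional difference D, and
    Pearson correlation), and a non-strict extreme-permutation counting rule.
    Also provides shift confidence intervals by test inversion, permutation
    inference for regression coefficients including the Freedman-Lane procedure
    for models with nuisance covariates, bundled example datasets, synthetic
    data generators, broom-style tidiers, ggplot2 visualisations of permutation
    null distributions, and a command-line interface.
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
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
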