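Package: pfdaudit
Title: Audit Tools for Phylogenetic Discriminant Classification of Bone
    Compactness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for auditing lifestyle classification of
    extinct and extant amniotes from bone compactness (Cg) and bone diameter
    (MD): a two-class phylogenetic flexible discriminant analysis (pFDA) core
    with Pagel's lambda generalized-least-squares whitening, taxon-resampling
    bootstrap with bias-corrected-and-accelerated (BCa) confidence intervals
    over random branch-length tree ensembles, classification performance
    metrics (accuracy, balanced accuracy, Matthews correlation, an equivalent
    random-classification heuristic), Monte Carlo sample-size power studies,
    distribution-fit model selection by AICc with Akaike weights, variance
    equivalence tests, Hopkins clustering-tendency statistics with Beta and
    Monte Carlo nulls, rank-permutation and exact binomial composition tests,
    compactness-variation statistics, and synthetic-data generators that give
    every pipeline stage a self-contained test surface.
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
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    MASS,
    car,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
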