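Package: pgenmi
Title: Probabilistic Integration of Cis-Regulatory Evidence with Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the pGENMi family of models for integrating
    transcription-factor binding evidence, filtered by dynamic epigenomic
    marks, with differential-expression p-values. Per-gene p-values are
    modelled as a two-component mixture of a Uniform(0,1) background and a
    Beta(alpha,1) enriched component, with the mixing prior a logistic
    function of weighted binary cis-regulatory evidence (pGENMi) or of
    factorized TF-by-mark weights (fw-pGENMi). Provides evidence-matrix
    construction from peak files under six encoding strategies, model
    fitting by penalized maximum likelihood, TF ranking by log-likelihood
    ratio drop, posterior-odds target scoring, permutation nulls,
    cross-validation, and model-faithful data simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
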