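Package: lexpred
Title: Language-Model and Cloze Predictability Effects on Word Viewing Times
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Compares cloze completion probability with three probabilistic
    language models (a Kneser-Ney smoothed trigram model, a latent Dirichlet
    allocation topic model queried incrementally over sentence prefixes, and a
    simple recurrent Elman network) as predictors of word viewing times in
    sentence reading. Provides synthetic generators for topic-structured
    training corpora, multinomial cloze norms and gamma-distributed fixation
    events; readers and writers for stimulus, cloze and fixation tables;
    single-fixation duration, gaze duration and total viewing time extraction
    with the standard cutoffs; logit and log10 predictor transforms with
    present/last/next-word alignment; and a generalized additive model
    comparison ladder (gamma family, log link, thin-plate smooths) with GCV,
    adjusted R-squared increments, deviance differences and chi-square tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    mgcv,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
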