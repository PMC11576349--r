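Package: fvgen
Title: Generative Language Modelling of Paired Antibody Fv Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for training and evaluating autoregressive language models
    of paired antibody variable domains (VH/VL). Provides a decoder-only
    transformer with rotary position handling trained in both sequence
    directions, temperature and nucleus (top-p) sampling with likelihood
    filtering, staged finetuning including developability-biased finetuning,
    a panel of repertoire evaluation statistics (nearest-neighbour Hamming
    novelty, embedding cosine diversity, VH-VL somatic-hypermutation
    correlation, pairing-likelihood discrimination, zero-shot
    perplexity-fitness correlation), and a fully seeded synthetic
    paired-repertoire simulator used as the test bed for every component.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
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
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
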