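Package: saccadeCI
Title: Bayesian Causal Inference for Trans-Saccadic Spatial Constancy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generative modeling and fitting of saccadic suppression of
    displacement (SSD) localization data through Bayesian causal inference.
    Implements a 2D mixture model in which a remapped presaccadic memory
    percept and a postsaccadic visual percept are either integrated with an
    allocentric prior (common cause) or segregated (independent causes),
    weighted by the inferred probability of a common cause. Provides the
    factorial SSD experiment design and pooling conventions, a trial-level
    synthetic-data generator, three response rules (mixture, model
    selection, probability matching), a simulation-based binned likelihood
    with multi-start Nelder-Mead maximum-likelihood fitting, response-rule
    model comparison, and summary curves (localization error versus
    displacement, inferred common-cause probability).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
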