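Package: lmencode
Title: Training-Scale Effects in Language-Model Encoding Models of Brain and Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how the amount of language-model training
    affects alignment with human neural and behavioral responses. Provides a
    small causal (unidirectional-attention) transformer language model with
    controlled initialization, checkpointed training and exact token-budget
    accounting; sliding-window perplexity evaluation; cross-validated linear
    encoding models mapping layer activations to fMRI voxel responses with
    noise-ceiling normalization, layer sweeps and voxel-group breakdowns;
    reading-time predictivity with constrained word-level cross-validation;
    corpus characterization (PTB-style tokenization, unique n-gram counts,
    benchmark contamination checks); and synthetic benchmark generators with
    analytically known entropy rates and noise ceilings so the full pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
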