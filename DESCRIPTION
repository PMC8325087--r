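Package: emoattn
Title: Emotion-Based Attention Networks for Depression Detection in Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects depression-indicative posts in social-media text with a
    two-branch neural classifier. A semantic branch encodes the full post with
    a bidirectional long short-term memory network and additive attention
    pooling; an emotion branch encodes the positive-word and negative-word
    sub-sequences selected by a word-polarity lexicon with twin encoders and
    fuses them through a learnable convex gate. Includes hand-written batched
    backpropagation with Adam, stratified k-fold cross-validation, ablation
    variants, corpus emotion statistics, and a synthetic labeled-corpus
    generator that emulates the class imbalance and per-class emotion-word
    rates of depression-forum data, so the whole pipeline runs without any
    external corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
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
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
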