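Package: metabnn
Title: Metaplastic Binarized Neural Networks for Continual Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Trains binarized neural networks whose real-valued hidden
    weights act as metaplastic consolidation variables: optimizer updates
    that oppose a synapse's current binary sign are attenuated by
    1 - tanh^2(m * W), alleviating catastrophic forgetting in sequential
    multitask and stream learning without task-dependent loss terms.
    Includes the analytically tractable quadratic binary task justifying
    the rule, consolidation baselines (elastic weight consolidation on
    binary weights, random importance, learning-rate decay, path-integral
    importance), permuted-task and stream-shard protocols with synthetic
    data generation and IDX dataset readers, and a multi-timescale
    chain-synapse extension.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
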