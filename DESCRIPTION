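Package: bsr
Title: Bowel Sound Recognition with a Branchformer Encoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: An end-to-end toolkit for recognising bowel sounds in abdominal
    audio recordings. Provides the standard short-time preprocessing chain
    (segmentation, peak normalisation, pre-emphasis, window framing), three
    acoustic feature families (mel-frequency cepstral coefficients, linear
    predictive coding, log mel-spectrum), a Branchformer encoder that runs a
    multi-head self-attention branch and a convolutional-gating MLP branch in
    parallel, four reference baseline models (CNN, LSTM, CNN+LSTM, ResNet-34),
    layer-freezing fine-tuning strategies for pretrained encoders, a
    reproducible hyperparameter sweep runner with Mann-Whitney U comparisons,
    and a synthetic burst-over-noise audio generator so the whole pipeline can
    be exercised without any external dataset. All models are trained with a
    built-in reverse-mode automatic differentiation engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    ggplot2,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
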