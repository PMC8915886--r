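Package: datm
Title: Discourse Atom Topic Modeling in Word Embedding Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discover latent topics in a corpus as sparse-dictionary atoms of a
    word-embedding space (K-SVD with orthogonal matching pursuit), map observed
    text spans onto those topics through the smooth-inverse-frequency (SIF)
    maximum a posteriori estimate of the latent discourse vector, and measure
    how topics load on latent semantic dimensions such as a gender axis built
    from anchor word pairs. Includes model-selection metrics (coherence,
    distinctness, reconstruction R-squared), a generative-model corpus
    simulator with planted atoms and a planted semantic axis for end-to-end
    validation, and downstream description tools: topic prevalence by group,
    prevalence ratios, loading-vs-prevalence rank correlation, and logistic
    regression on binary topic presence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
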