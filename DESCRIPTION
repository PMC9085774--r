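Package: ipdinfer
Title: Strategy Inference for Long Iterated Prisoner's Dilemma Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers behavioral strategies from long Iterated Prisoner's
    Dilemma (IPD) experiments. Round-by-round actions are encoded as
    conditional actions over the eight (previous-round context, action)
    symbols, players are grouped by a two-level K-means clustering
    (contextual clusters on context counts, behavioral sub-clusters on
    conditional cooperation counts) with elbow-based model selection and
    silhouette diagnostics, and each sub-cluster's pooled symbol sequences
    are summarized by a left-to-right multinomial hidden Markov model
    trained with a constrained Baum-Welch algorithm. A cohort simulator of
    noisy stochastic memory-one strategies (AllC, AllD, TFT, GTFT, WSLS,
    Grim, Random) under fixed- and shuffled-partner matching makes the whole
    pipeline testable end to end with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    knitr,
    mclust,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
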