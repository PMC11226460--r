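Package: vlmcdrive
Title: Context Tree Models and Stimulus-Driven Response Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for variable-length Markov chains (context tree models)
    over small categorical alphabets and for paired stimulus/response trial
    sequences in which the response at each trial is driven by the context
    of the stimulus past. Provides simulation of stimulus chains and of
    matching, maximizing and suboptimal responder agents; entropy rates,
    stationary distributions and theoretical matching/maximizing scores via
    a first-order Markov embedding; a BIC context-tree estimator for driven
    response sequences with recursive pruning, an exhaustive-search oracle
    and penalty tuning by final-prediction-error risk; mode (consensus)
    context trees; sliding-window performance scoring with kernel-density
    strategy classification; and a likelihood-ratio test of whether
    responses depend on the responder's own past beyond the stimulus past.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
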