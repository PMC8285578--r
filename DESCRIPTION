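Package: choicegain
Title: Choice-Induced Changes in Temporal Evidence Weighting for Sequential Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling how an intermittent categorical choice changes
    the weighting of decision evidence in two-interval estimation tasks.
    Implements probit psychometric fitting, Global Gain and choice-based
    Selective Gain estimation models with choice-conditioned truncated-Gaussian
    convolution likelihoods and bootstrap confidence intervals, model-free ROC
    sensitivity indices, paired sign-flip permutation tests and repeated-measures
    ANOVA interactions, Fisher-pooled bootstrap correlations, a model-recovery
    control based on choice-matched rejection sampling, and a pupillometry
    preprocessing chain (blink interpolation, event-response deconvolution,
    Butterworth band-pass filtering, epoching, cluster-based permutation tests).
    Includes generators for synthetic task schedules, observers and pupil traces
    so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
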