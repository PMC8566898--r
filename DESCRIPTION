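Package: stressrl
Title: Acute Stress Effects on Reinforcement Learning and Striatal
    Prediction-Error Signalling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tested re-implementation of a model-based fMRI analysis of
    reinforcement learning under acute stress. Provides the probabilistic
    gain/loss task generator, a dual-learning-rate Q-learning model with
    softmax choice (simulation, likelihood and latent prediction-error
    traces), multi-start maximum-likelihood fitting with parameter
    recovery, trial-wise behavioural statistics (responder filtering,
    repeated-measures ANOVA, mixed-effects logistic regression, planned
    contrasts, learning curves), a first-level GLM on ROI-averaged BOLD
    time series with canonical-HRF parametric modulators, discrete-cosine
    high-pass filtering and AR(1) prewhitening, second-level tests of
    stress-induced blunting, subsidiary quartile-bin and sign-split
    models, and a synthetic-cohort generator emulating the behavioural,
    self-report and BOLD structure the analysis assumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
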