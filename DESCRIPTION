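Package: memloop
Title: Simulation and Analysis of Closed-Loop Memory Stimulation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse closed-loop brain stimulation
    experiments in delayed free recall. Generates synthetic multi-session
    event tables, spectral power features and raw intracranial EEG with a
    subsequent-memory effect; preprocesses raw signal (band-stop filtering,
    bipolar re-referencing, Morlet wavelet power, z-score normalization);
    trains per-subject L2-penalized logistic recall classifiers with
    forward-model feature attribution and permutation testing; simulates
    threshold-triggered closed-loop stimulation sessions with online
    normalization updates and matched-control bookkeeping; and estimates
    stimulation effects on recall and decoded brain state with binomial
    mixed-effects, log-binomial and linear mixed models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    lme4,
    sandwich,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
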