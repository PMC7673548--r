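Package: taskbold
Title: Simulation and Analysis of Task-Related BOLD Activity in Visual Cortex
Version: 0.1.0
Authors@R:
    person("taskbold", "developers", email = "taskbold@example.org", role = c("aut", "cre"))
Description: Tools for quantifying stimulus-independent, task-entrained BOLD
    responses in early visual cortex. Provides a generative model of
    trial-locked fMRI sessions with three dissociable noise sources (ongoing
    1/f fluctuations, per-trial amplitude jitter, per-trial temporal jitter),
    a shared heart-rate-driven global component, and pupillometric traces;
    the standard preprocessing chain (intensity normalization, z-scoring,
    global signal regression); cosine-fit coherence and phase maps; trial
    averaged amplitude and latency metrics; three trial-to-trial variability
    statistics including the circular standard deviation of response phase;
    group-level label-permutation inference; a noise-source simulation study;
    pulse-to-BOLD kernel estimation; tonic and phasic pupil quantification;
    and a population-receptive-field weighted projection of responses onto
    the visual field.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
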