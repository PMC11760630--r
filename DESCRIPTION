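Package: predistract
Title: Simulation and Analysis of Distractor Predictability Under Load in
    Auditory Spatial Attention EEG Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to generate, simulate and analyse a dual-stream auditory
    spatial n-back experiment in which distracting spoken items follow either
    a predictable (repeating) or an unpredictable (constrained random)
    sequence, crossed with perceptual load (target-to-distractor SNR) and
    working-memory load (1- vs 2-back). Provides a validated experiment-plan
    generator with the design's transition-probability structure; a
    synthetic-data module producing button-press behaviour from known
    signal-detection parameters and 64-channel epoched EEG containing 1/f
    noise, lateralised ~10-Hz alpha oscillations and evoked components with
    condition-dependent amplitudes; deterministic epoch preprocessing
    (zero-phase band-pass filtering, amplitude-based trial rejection,
    re-referencing, baseline correction); signal-detection analysis (d-prime
    and criterion with extreme-rate correction); single-trial event-related
    potential mixed-effects models with Satterthwaite degrees of freedom and
    standardised partial effect sizes; moving-window FFT time-frequency
    power with attentional-modulation and alpha-lateralisation indices,
    FDR-based time-window selection and repeated-measures ANOVA; and an
    end-to-end seeded pipeline for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    lmerTest,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
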