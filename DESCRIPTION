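Package: entrainSL
Title: Neural Entrainment Analysis of Auditory Statistical Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frequency-tagging analysis of statistical word learning from
    continuous artificial-language speech streams. Builds trisyllabic-word
    exposure and target-detection streams with verifiable transitional
    probability structure, simulates entrained multichannel EEG with known
    ground truth, and implements the full analysis chain: zero-phase
    filtering, mastoid re-referencing, word-locked epoching, inter-trial
    phase coherence (ITC) spectra, the Word Learning Index (WLI =
    word-rate ITC / syllable-rate ITC), onset-jitter surrogate nulls,
    sliding-bundle learning time courses with linear mixed-effects slope
    tests, and scoring of rating, two-alternative forced-choice, and
    target-detection behavioural tasks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
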