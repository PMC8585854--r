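Package: pergss
Title: Steady-State Pattern Electroretinogram Simulation and Group Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and analyses steady-state pattern electroretinogram
    (PERG) recordings for two-group clinical comparisons. Provides a
    synthetic cohort generator with sweep-level waveforms, artifact
    rejection and stimulus-synchronized averaging, discrete-Fourier
    amplitude and phase extraction with adjacent-bin noise correction,
    phase-to-response-time conversion with a deterministic cycle-ambiguity
    rule, and the full inference layer: split-plot repeated-measures ANOVA
    with Greenhouse-Geisser correction, estimated-marginal-mean group
    contrasts with pooled error, Hedges-corrected effect sizes,
    Bonferroni-Holm adjustment, and check-size ratio normalization.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
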