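Package: vowelvar
Title: Trial-to-Trial Formant Variability Under Delayed Auditory Feedback
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for quantifying feedforward variability in
    vowel production from single-word recordings made under normal and delayed
    auditory feedback. Provides a source-filter vowel synthesizer for building
    fully ground-truthed synthetic cohorts (stuttering and nonstuttering
    groups), LPC formant tracking with dynamic-programming candidate selection,
    Mel-scaled trial-to-trial and within-trial formant variability metrics over
    the feedforward (first 50 ms) window, secondary measures (vowel duration,
    intensity, inter-vowel distance), and an exact balanced split-plot mixed
    ANOVA (vowel x condition x group with participant random intercepts) with
    Tukey-adjusted post-hoc contrasts and simple effects.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest,
    emmeans,
    withr
Config/testthat/edition: 3
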