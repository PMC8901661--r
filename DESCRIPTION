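Package: vocalence
Title: Emotional Valence and Context Classification of Pig Vocalizations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying pig vocalizations by emotional valence
    (positive/negative) and context of production. Implements extraction of
    ten acoustic parameters (duration, amplitude-modulation measures,
    spectral energy quartiles, peak frequency, harmonic-to-noise ratio and
    Wiener entropy) from cropped call recordings, low-/high-frequency call
    typing by age-specific spectral centre-of-gravity cutoffs, PCA-based
    parameter screening with Gaussian mixed models and marginal R-squared,
    permuted discriminant function analysis (pDFA) with pig identity as a
    control factor, a spectrogram convolutional network classifier with
    repeated-trial metrics, and t-SNE maps of network activations. A
    parametric synthetic-call generator reproduces the statistical
    structure of the study conditions so the whole pipeline is testable
    without audio downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    MASS,
    lme4,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
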