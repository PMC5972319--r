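Package: pulsescreen
Title: Fingertip Pulse-Wave Screening for Depression via Heart Rate Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for autonomic-transient-response
    screening of major depressive disorder from fingertip
    photoplethysmography (PPG). Converts a raw pulse waveform to peak-to-peak
    intervals, to time-resolved spectral heart-rate-variability series (HR,
    HF power, LF/HF ratio) via cubic-spline tachogram resampling and
    sliding-window Fourier band integration, to a nine-feature vector of
    phase averages around a mental task, and to a linear logit screening
    score. Ships the published frozen screening coefficients, a
    ridge-stabilised logistic trainer with leave-one-out cross-validation,
    validation statistics (paired-method agreement, group difference tests,
    randomized quantile residual diagnostics with an Anderson-Darling
    normality check), and an integral-pulse-frequency-modulation simulator
    so every stage is exercisable on synthetic signals without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
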