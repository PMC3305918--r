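Package: hrvstress
Title: Nonlinear Heart Rate Variability Analysis and Real-Life Stress Detection
Version: 0.1.0
Authors@R:
    person("HRV", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Short-term (5-minute) nonlinear heart rate variability analysis
    from RR-interval series: Poincare plot descriptors (SD1, SD2), approximate
    entropy under three tolerance choices (0.2*SDNN, entropy-maximising r, and
    the Chon regression formula), correlation dimension, detrended fluctuation
    analysis (alpha1, alpha2), and recurrence quantification (REC, DET, ShEn,
    mean and maximal diagonal line length). Includes paired rest-versus-stress
    descriptive statistics with the Wilcoxon signed-rank test, a linear
    discriminant stress classifier with subject-wise k-fold cross-validation
    and exhaustive feature-subset search, and a calibrated synthetic generator
    of paired 5-minute RR recordings for end-to-end testing without ECG data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
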