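Package: fnirswm
Title: Simulation and Analysis Pipeline for fNIRS Working-Memory Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing functional near-infrared
    spectroscopy (fNIRS) experiments on working memory in a pre/post
    intervention design. Provides a synthetic-data generator for
    dual-wavelength optical recordings over a fronto-parietal montage and
    for n-back behavioral sessions; a channel-space preprocessing chain
    (optical density conversion, cardiac-peak channel quality control,
    wavelet motion-artifact correction, zero-phase Butterworth band-pass
    filtering, modified Beer-Lambert inversion with an age-dependent
    differential pathlength factor, block averaging, and z-score channel
    outlier exclusion); behavioral scoring via the rate-correct score with
    trial filters and a binomial inclusion criterion; region-of-interest
    pooling; and the inference stage (mixed repeated-measures ANOVA with
    Greenhouse-Geisser correction and generalized eta squared, planned
    contrasts, Welch pairwise comparisons, and forced-entry multiple
    regression).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
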