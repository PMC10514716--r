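Package: audsynth
Title: Quantification of Evoked EPSC Trains and Auditory Cortical Tuning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying optogenetically evoked AMPAR EPSC trains
    recorded in whole-cell voltage clamp (per-pulse peak-to-trough amplitudes,
    single-exponential decay time constants, paired-pulse ratios, steady-state
    depression, normalization schemes, series-resistance quality control) and
    sound-evoked calcium responses of cortical neurons imaged in awake mice
    (delta-F/F, Z-scored transient detection, frequency-response areas, best
    frequency, response threshold, Q20 bandwidth, d-prime ranking, wide-field
    tonotopy maps).  Includes seeded synthetic-data generators emulating both
    recording modalities with known ground truth, a paired-comparison
    statistical decision tree with Holm-Bonferroni correction, and end-to-end
    experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    nortest,
    minpack.lm,
    EBImage
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
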