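Package: thermolabor
Title: Labor-Onset Forecasting from Continuous Skin Temperature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for anticipating the onset of human labor from wearable
    finger skin-temperature time series. Provides a synthetic cohort generator
    emulating pre-labor thermal signatures (circadian damping, a pre-labor
    temperature drop, non-wear gaps, and ten-day urinary hormone trajectories),
    preprocessing of per-minute temperatures into daily 288-slot vectors with
    inclusion filters, generalized Morse-wavelet circadian power analysis,
    Mann-Kendall trend and nonparametric group tests, a convolutional
    autoencoder plus masked LSTM regressor predicting days until labor onset,
    and subject-wise cross-validation with kernel-density-calibrated
    prediction windows and clinical TP/FP/FN window accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
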