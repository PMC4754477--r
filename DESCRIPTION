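Package: wafecg
Title: Wavelet-Packet Average-Framing Energy Features for ECG Rhythm
    Confirmation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and threshold-based rhythm confirmation for
    single-lead ECG segments. Segments are decomposed with a level-5
    wavelet-packet filter bank (Daubechies wavelets, periodized boundary);
    each terminal subband's percentage energy is computed over short frames
    and frame-averaged into a 32-dimensional feature vector (WAFE).
    Congestive-heart-failure-like rhythms are confirmed against a background
    rhythm by three jointly required scores: a percentage root-mean-square
    difference ratio, a log distance ratio, and a correlation-coefficient
    ratio. Includes comparison extractors (wavelet-packet Shannon,
    log-energy and SURE entropies, and mean Welch power spectral density),
    a synthetic PQRST segment generator for four rhythm classes, additive
    white Gaussian noise injection at exact SNR, and an evaluation harness
    (sensitivity, specificity, positive predictivity, recognition rate,
    ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
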