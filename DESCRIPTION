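Package: dynfc
Title: Dynamic Functional Connectivity and Wavelet Coherence Features
    for Clinical Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Extracts static and dynamic interaction statistics between
    functional brain network time-series - Fisher-z static connectivity,
    tapered sliding-window dynamic connectivity, and wavelet-coherence
    derived statistics (number of coherence clusters, lead coherence) -
    together with task activation features, and feeds them into a nested
    leave-one-out prediction stack (class-weighted linear SVM with
    per-fold SVM-RFE or Kruskal-Wallis feature selection, LOOCV multiple
    regression, soft-voting and prediction-averaging ensembles, full-data
    backward elimination) that maps baseline features to 3- and 6-month
    change in depression severity. Includes multi-echo signal combination,
    zero-phase Butterworth filtering, and a synthetic cohort generator
    with planted coherence epochs and a known outcome model so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
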