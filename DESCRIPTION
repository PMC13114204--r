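Package: coseize
Title: Patient-Specific Seizure Detection from Scalp EEG with Multiscale
    Cosine Convolution Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects epileptic seizures in multichannel scalp EEG using a
    compact convolutional network whose temporal filters are cosine
    parameterized: each kernel of length k is generated from just two
    learnable parameters, an amplitude and an angular frequency. The
    package provides EDF recording input/output with bipolar montages,
    Daubechies-4 wavelet sub-band filtering (4-32 Hz), sliding-window
    segmentation with ictal oversampling, a multiscale cosine convolution
    front end combined with heterogeneous two-stream feature modules, full
    CPU training with Adam and a stepped learning-rate schedule, score
    post-processing (moving-average smoothing, thresholding, collar
    extension) with per-patient calibration, segment- and event-based
    evaluation including false-detection rate per hour and AUROC, gradient
    class-activation (Grad-CAM) heatmaps for interpretation, and a
    synthetic EEG generator with exact ground-truth annotations so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    pROC,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
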