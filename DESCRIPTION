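Package: bcgcycle
Title: Ballistocardiography Cardiac-Cycle Analysis and Heart-Failure
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing single-channel ballistocardiography (BCG)
    vibration recordings. Implements discrete-wavelet-transform (sym4)
    multiresolution extraction of the 0.5-35 Hz BCG band, detection of the
    seven Starr fiducial points (H, I, J, K, L, M, N) per heartbeat,
    cardiac-cycle phase categorization into IVCT/LVET/IVRT/NH intervals,
    nine-parameter feature extraction with dynamic-time-warping beat
    averaging, and five-fold cross-validated heart-failure classification
    with six standard models. A synthetic BCG/ECG generator with exact
    per-beat ground truth makes every pipeline stage verifiable without
    recorded patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    class,
    e1071,
    rpart,
    randomForest,
    xgboost,
    pROC
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
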