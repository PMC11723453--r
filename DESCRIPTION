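Package: rowkinetics
Title: Estimating Rowing Forces and Segment Powers from Kinematic Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for estimating the forces and segment powers produced
    during ergometer and scull-boat rowing from kinematic-only sensing
    (cable position sensors on the ergometer; body-worn IMUs plus GPS on the
    boat). Includes a synthetic rowing-session generator with known
    ground-truth kinetics, sensor-stream preprocessing (drift-removed
    integration, cross-correlation synchronization, cycle segmentation,
    drive-phase detection), the handle/gate and arms-trunk-legs power
    decomposition, per-cycle feature assembly, a sequence-to-sequence LSTM
    regressor trained with Adam and early stopping (implemented in C++),
    and evaluation metrics (drive-phase MAE and cycle-averaged MAE,
    technique determinants T2P/M2P/WR, and t-test based technique
    discrimination accuracy).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    pracma,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
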