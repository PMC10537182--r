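Package: wavestate
Title: Ensemble Wavelet Decomposition for EEG Mental-State Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of focused, unfocused and drowsy mental states from
    multichannel EEG recordings using an ensemble of three wavelet filter
    banks: the multilevel discrete wavelet transform (MDWT), the tunable
    Q-factor wavelet transform (TQWT) and the flexible analytic wavelet
    transform (FAWT). Provides perfect-reconstruction forward and inverse
    transforms, a bank of 27 statistical and nonlinear subband features,
    minimum-redundancy maximum-relevance (mRMR) feature ranking with
    cross-transform feature fusion, optimizable ensemble classifiers
    (bagged trees, boosted trees, RUSBoost, random-subspace k-NN and
    discriminant) evaluated under holdout, five-fold and ten-fold
    cross-validation with iterative majority voting, and a synthetic
    multichannel EEG generator with state-dependent rhythm-band power so
    the full pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    rpart,
    MASS,
    class,
    signal,
    yaml,
    jsonlite,
    pROC
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
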