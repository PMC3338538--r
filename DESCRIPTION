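Package: mvpadecode
Title: Multiclass fMRI Decoding with SVM and Gaussian-Process Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multi-voxel pattern analysis of paced and self-paced fMRI
    sessions: signal extraction with hemodynamic-delay correction and
    overlap exclusion, two-level feature selection (omnibus-F GLM filter
    plus recursive feature addition driven by support-vector weights),
    linear support-vector-machine and expectation-propagation
    Gaussian-process binary classifiers, error-correcting output-code
    multiclass assembly, balanced-accuracy evaluation under
    leave-one-block-out cross-validation with within-block permutation
    testing, and rank-based procedure-comparison statistics. Includes a
    synthetic-data generator emulating a three-category maze-exploration
    session and an imbalanced self-paced mental-imagery session so the
    whole pipeline is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
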