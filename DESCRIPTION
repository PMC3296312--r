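Package: svsfusion
Title: Binary Label Fusion with Dissimilarity-Based Strategy Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for fusing multiple binary segmentations ("labels") of the
    same 2D or 3D scene into a single consensus segmentation. Implements three
    base fusion algorithms (majority Vote, the STAPLE expectation-maximization
    estimator of the hidden true segmentation and per-rater performance, and
    Shape-Based Averaging over signed Euclidean distance maps), ground-truth
    free dissimilarity estimators built from binomial majority probabilities,
    and a trained selector (SVS) that picks the most appropriate fusion method
    per case from fitted scoring surfaces. Also provides deformable ellipse
    and ellipsoid simulators for generating calibrated synthetic rater labels,
    evaluation metrics (relative difference area and Dice coefficient), and an
    end-to-end simulation protocol for training and benchmarking the selector.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    png,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
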