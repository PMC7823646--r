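Package: depthparts
Title: Feature-Based Determination of Dairy-Cow Body Parts in Depth Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pixel-level classification of dairy-cow body parts (head, rump,
    back, legs, udder) in Kinect-style depth maps. Five per-pixel properties
    (row, column, depth, discrete mean curvature, local variance) feed a
    k-nearest-neighbour classifier with cross-validated grid search and a
    dense feed-forward neural network, with SMOTE class balancing inside
    every resampling loop and one-vs-rest evaluation (precision, recall, F1,
    accuracy, Hamming loss, Kruskal-Wallis comparisons). A seeded synthetic
    depth-scene generator renders labelled cow-like composites of quadric
    primitives from the recording unit's three camera positions, so the full
    pipeline is reproducible without barn recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
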