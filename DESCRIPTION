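Package: fcmanifold
Title: Riemannian Manifold Analysis of Task-Based Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracking large-scale reorganisation of functional
    connectivity during motor learning. Implements affine-invariant Riemannian
    operations on symmetric positive-definite covariance matrices (geometric
    means, tangent projection, parallel transport, and subject-level
    centering), construction of low-dimensional connectivity manifolds
    (row thresholding, cosine affinity, PCA embedding, Procrustes alignment)
    with per-region eccentricity, region- and network-level inference
    (repeated-measures ANOVA, FDR, paired contrasts, k-means functional
    ensembles, reinstatement representational similarity analysis, and
    spin-test spatial permutations), and a behavioural pipeline (trial QC,
    learning-curve binning, savings, recall ratio, and a functional-PCA
    learning score). A seeded synthetic-data generator with known ground
    truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
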