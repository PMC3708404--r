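Package: ltcoding
Title: Linear Tensor Coding for Statistical Texture Modeling of Volumetric
    Image Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Greedy rank-one tensor decomposition (linear tensor coding) for
    ensembles of co-registered volumetric images, together with its
    multilinear-subspace baseline (generalized N-dimensional PCA, a shared
    Tucker model fit by alternating per-mode eigendecompositions), a
    statistical texture model over the learned coefficients, and
    correlation-driven selection of discriminative bases for two-class
    classification of volumes with leave-one-out SVM and k-nearest-neighbour
    evaluation. Includes a seeded generator of synthetic volume ensembles
    with planted low-rank structure, readers and writers for NIfTI volume
    stacks, model persistence, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    class,
    e1071,
    jsonlite,
    optparse,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
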