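Package: pfasqsar
Title: QSAR and Read-Across Modelling of PFAS Binding to Human Serum Albumin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Classification and regression QSAR workflow for modelling the
    binding affinity (EC50) of per- and polyfluoroalkyl substances (PFAS) to
    human serum albumin from 2D molecular structure. Computes topological
    descriptors (average path connectivity, eccentricity dispersion,
    bond-order-augmented edge-adjacency eigenvalues, Moran and Geary
    autocorrelations, packing density index, quantitative estimate of
    drug-likeness) from SMILES, fits Fisher discriminant and MLR/PLS models
    with genetic-algorithm descriptor selection and an exhaustive double
    cross-validation workflow for small datasets, provides a full battery of
    classification and regression validation metrics, a standardization-based
    applicability domain, and a generic similarity-weighted read-across
    scorer. Ships the curated 24-compound PFAS study dataset and functions to
    reproduce its published summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
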