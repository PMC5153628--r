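Package: cosine
Title: One-Class Collaborative Filtering for Multi-Target Virtual Screening
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein-chemical interactions at genome scale by
    completing a sparse binary interaction matrix with weighted, imputed
    logistic matrix factorization. Latent factors for proteins and chemicals
    are dually regularized by graph-Laplacian penalties built from
    protein-sequence and chemical-structure similarity, the loss is minimized
    with AdaGrad in a two-pass scheme that re-weights and imputes entries
    from first-pass probabilities, and brand-new chemicals or targets with no
    interaction data are handled through a similarity-weighted latent profile
    (cold start). Includes readers for tab-delimited interaction and
    similarity matrices, a synthetic benchmark generator with controllable
    low-rank and homophily structure, and evaluation protocols (chemical-wise
    cross-validation, leave-one-out Top-1, true-positive rate at top r
    percent under cold-start stratification).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
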