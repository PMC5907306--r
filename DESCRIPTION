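Package: ddinmf
Title: Signed Drug-Drug Interaction Prediction via Semi-Nonnegative
    Matrix Factorization
Version: 0.1.0
Authors@R:
    person("DDI", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Predicts conventional (binary) and comprehensive (signed:
    enhancive/degressive) drug-drug interactions for new drugs from their
    feature vectors. Training factorizes the interaction adjacency matrix
    by nonnegative matrix factorization (binary networks) or
    semi-nonnegative matrix factorization (signed networks) and regresses
    drug features onto the latent encoding matrix with SIMPLS partial
    least squares; prediction maps new-drug features into the latent
    space and reconstructs interaction scores. Also provides Gaussian
    kernel PCA feature reduction, cold-start cross-validation with
    AUROC/AUPR and their signed extension, top-k hitting ratios,
    signed-triangle balance censuses, latent-space embeddings of the
    factor matrices, and a planted-community signed-network simulator
    with feature matrices coupled to community structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
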