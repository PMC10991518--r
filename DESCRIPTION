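Package: contiglm
Title: Masked Language Modeling of Gene Order in Microbial Contigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a transformer encoder on multi-gene contigs in which each
    gene is a token built from a fixed protein embedding plus an orientation
    flag, using a masked-token objective with a multi-prediction head and a
    likelihood simplex. Provides the full surrounding toolkit: a synthetic
    corpus generator with planted gene families, operon blocks, contextual
    co-occurrence rules and interacting gene pairs; corpus normalization,
    PCA-whitened label construction and masking; pseudo- and absolute-accuracy
    evaluation with confidence analysis; contextualized embedding and
    symmetrized attention extraction; and downstream statistics including
    attention-operon correlation, cross-validated operon and taxonomy
    classifiers, closed-form Gaussian Kullback-Leibler divergences with
    Mahalanobis outlier filtering, context-variance of gene embeddings,
    linear probes, and paralog matching against a random-prediction null.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet,
    cluster,
    e1071
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
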