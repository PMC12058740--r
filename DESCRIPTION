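Package: sdeval
Title: Evaluation of Synthetic Tabular Health Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates synthetic tabular data against the real data it
    imitates, across fidelity (per-attribute Hellinger distances, pairwise
    correlation difference over a phi-k style mixed-type association matrix,
    depth-vs-depth plot R-squared, out-of-bag AUC-ROC distinguishability),
    machine-learning utility (train-real/test-real versus
    train-synthetic/test-real over five model families), privacy risk
    (singling out, linkability, membership and attribute inference with a
    held-out control baseline), and a single fidelity-utility tradeoff score.
    Includes a seeded mixed-type fixture generator with known latent
    correlation structure and Gaussian/empirical copula baseline generators,
    plus a fold-based evaluation runner with best/worst/mean aggregation and
    paired model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    mvtnorm,
    randomForest,
    rpart,
    e1071,
    nnet,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
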