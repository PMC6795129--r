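Package: nnlda
Title: Neural Link Prediction for lncRNA-Disease Associations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts long non-coding RNA (lncRNA) to disease associations from a
    sparse binary bipartite association matrix. Implements a neural matrix
    factorization scorer (NNMF: shared embeddings, sigmoid of the dot product,
    cross-entropy loss) and its fused extension NNLDA, which concatenates an
    element-wise-product matrix-factorization part with a stack of ReLU
    fully-connected layers before a final sigmoid output. Training uses
    mini-batch Adam with negative sampling (four sampled non-associations per
    known association). Also provides a Gaussian interaction-profile KNN
    baseline, the full 10-fold cross-validation evaluation protocol with
    99-negative candidate ranking and Hit Ratio at k, latent-dimension and
    layer-depth parameter sweeps, a synthetic bipartite data generator with
    planted low-rank plus nonlinear structure, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
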