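Package: causalDR
Title: Network-Based Drug Repurposing over Signed Causal Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug repurposing candidates by propagating drug effects
    through a directed, signed, confidence-scored causal interaction network
    (a SIGNOR-style resource). Disease modules are selected from differential
    expression data with a network-weighted knode ranking followed by
    permutation-importance refinement of a K-nearest-neighbour classifier.
    Drug-disease associations are scored by summing signed shortest-path
    connection scores between drug targets and disease genes, with the sign
    flipping at every down-regulating edge and adjusted by drug mode of action
    and disease-gene fold-change direction. Statistical significance comes
    from a size-matched random-module null distribution. A synthetic-fixture
    generator produces all inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    e1071,
    pROC,
    class,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
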