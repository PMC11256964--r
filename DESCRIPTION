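Package: domseg
Title: Protein Domain Segmentation from Structure via Pairwise Co-Membership Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments protein 3D structures into domains. A fully
    convolutional dilated residual network predicts, for every pair of
    residues, the probability that they belong to the same domain; a greedy
    maximum-likelihood search resolves these pairwise probabilities into
    discrete (possibly discontinuous) domain assignments with a calibrated
    per-chain confidence score. Includes Calpha-only feature construction
    with a geometric secondary-structure assigner, CATH-style chopping
    string input/output, segmentation evaluation metrics
    (intersection-over-union, domain-level accuracy, boundary distance
    score), and a synthetic-structure generator with known domain labels
    for training and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
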