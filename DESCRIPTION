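Package: asmatch
Title: Alignment-Free Sequence Distance Estimation via Differentiable
    Approximate String Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates pairwise alignment distances between nucleotide
    sequences without performing alignments at comparison time.  A Siamese
    network whose core layer is a differentiable approximate-string-matching
    dynamic program with learnable pattern matrices and a learnable gap
    penalty embeds variable-length sequences into fixed-dimension vectors;
    cosine distances between embeddings are trained to regress onto
    Needleman-Wunsch alignment distances.  Includes the affine-gap
    Needleman-Wunsch reference machinery used to produce training targets,
    analytic gradients for the soft dynamic program, an evaluation protocol
    (mean relative error, nearest-neighbour taxonomy assignment), a
    synthetic amplicon-family generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    methods,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
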