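Package: depthlift
Title: Adversarial Depth Projection for Low-Depth Long-Read Variant Calling
Version: 0.1.0
Authors@R: person("depthlift", "maintainers", email = "depthlift@example.org",
    role = c("aut", "cre"))
Description: Germline small-variant calling from low-depth Oxford Nanopore
    alignments. Candidate sites are summarized as strand-aware counting pileup
    tensors (33 x 8 x 4), flattened to 33 x 32 images; an encoder-decoder
    generative network projects a low-depth image to its high-depth
    counterpart, a conditional discriminator supplies an adversarial training
    signal, and a bidirectional-LSTM multi-task classifier predicts genotype,
    zygosity and the two allele length changes, which are decoded to VCF.
    Includes a diploid read simulator with planted SNPs/indels and seeded
    read-level down-sampling, genotype-aware VCF benchmarking, and a
    command-line workflow (simulate, make-dataset, train, call, evaluate).
    All networks and losses are implemented in vectorized base R with
    explicit backpropagation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    optparse,
    Biostrings,
    Rsamtools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
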