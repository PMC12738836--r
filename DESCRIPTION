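Package: chloroleadr
Title: Classification and Interpretation of Chloroplast 5' Leader Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts 300-nt leader (5' UTR) sequences upstream of chloroplast
    coding sequences, partitions them by Shine-Dalgarno motif content, and
    classifies them (plant vs. alga, with vs. without SD) using a hybrid
    convolutional/recurrent neural network with channel attention, multi-head
    self-attention and residual connections, implemented natively in R.
    Includes a synthetic leader-sequence generator with planted-motif ground
    truth, stratified cross-validation and a full metric suite, and a
    formula-level interpretability toolkit: attention profiles, group saliency
    maps, perturbation (in silico mutagenesis) importance scores, sequence
    logos and k-mer abundance tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    Rcpp,
    generics,
    ggplot2,
    pROC,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    readr,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
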