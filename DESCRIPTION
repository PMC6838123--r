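Package: hicsubcomp
Title: Hi-C Subcompartment Inference from Imputed Inter-Chromosomal Contacts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers the five primary spatial subcompartments (A1, A2, B1,
    B2, B3) of 100 kb genomic bins from moderate-coverage Hi-C data. A
    denoising autoencoder imputes dense inter-chromosomal contact
    probabilities from sparse ones and yields low-dimensional latent
    embeddings of each bin's genome-wide contact profile; a balanced
    multilayer perceptron classifies the embeddings into subcompartments.
    Includes the contact-probability transform, binomial coverage
    downsampling, training-set balancing by within-class interpolation,
    cross-cell-type conservation states with annotation entropy and
    information content, evaluation utilities (confusion matrices, AUPR,
    cross-validation, enrichment fold change, boundary signal profiles,
    coverage titrations), and a planted-truth simulator for
    inter-chromosomal contact matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
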