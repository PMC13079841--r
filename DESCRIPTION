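Package: modamix
Title: Staged Adversarial Domain Adaptation for Multi-Omics Batch Correction and Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removes batch effects within and across omics modalities and
    integrates a labeled source multi-omics cohort with an unlabeled target
    cohort in a shared class-discriminative latent space, with label transfer
    to the target samples. Training proceeds in four stages: supervised
    pre-training of modality-specific feature extractors and classifiers,
    adversarial domain adaptation within each omics layer, adversarial
    alignment of the integrated multi-omics embedding, and semi-supervised
    refinement combining pseudo-labeling with class-level centroid alignment.
    Includes feature-engineering operators for expression, chromatin
    accessibility and DNA methylation data, a seeded synthetic multi-omics
    generator with planted class structure and batch effects, and clustering
    and classification evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    rlang,
    generics,
    ggplot2,
    glmnet,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite,
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
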