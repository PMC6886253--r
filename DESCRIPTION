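Package: ppimm
Title: Multimodal Representation Learning for Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts protein-protein interactions and classifies protein
    families by fusing two learned protein representations: deep
    physicochemical sequence features (amino-acid composition, grouped
    composition, conjoint-triad and quasi-sequence-order descriptors
    compressed by a stacked autoencoder) and topological node embeddings
    (continuous bag-of-words training over bounded random walks on the
    interaction graph). Includes balanced dataset construction with
    subcellular-location-aware negative sampling, supervised twin-branch
    interaction and multi-family classifiers, evaluation metrics with
    cross-validation, a synthetic fixture generator, and a command-line
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
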