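Package: synthspace
Title: Synthesizable Chemical Space Sampling, Retrosynthesis Corpora, and
    Analog Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for defining a synthesizable chemical space as a library of
    purchasable building blocks crossed with reaction-SMARTS templates, for
    sampling linear and branched synthesis routes from that space, for turning
    routes into retrosynthesis-ordered training records (JSONL), for
    benchmarking the chemical validity of model-generated retrosynthesis
    responses, and for reconstructing target molecules or ranked synthesizable
    analogs from predicted template sequences and building blocks via
    template-constrained nearest-neighbor search and forward template
    application. Chemistry primitives (SMILES canonicalization, SMARTS
    matching, reaction application, Morgan and pharmacophore fingerprints,
    Murcko scaffolds) are provided by RDKit through a persistent Python
    worker process.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: Python (>= 3.8) with the rdkit package, available as
    'python' on the PATH
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    processx,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
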