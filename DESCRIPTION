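Package: phoregen
Title: Pocket-Conditioned Generation of 3D Pharmacophores by Equivariant Diffusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates three-dimensional pharmacophores conditioned on a
    protein binding pocket with an E(3)-equivariant denoising diffusion
    model over heterogeneous pocket-pharmacophore graphs. Includes
    interaction-pharmacophore extraction from protein-ligand complexes,
    3-8 center subsampling augmentation for training data, a geometric
    vector perceptron style graph denoiser trained with Adam, ancestral
    sampling, pharmacophore matching against multi-conformer ligand
    libraries by rigid least-squares superposition, enrichment-factor and
    precision/recall/F1 scoring, query-size filtering, UFF conformer
    strain energies, and a synthetic-fixture generator with planted
    ground truth for end-to-end testing without external datasets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    readr,
    bio3d,
    ChemmineR,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
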