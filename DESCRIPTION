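Package: chromfold
Title: Integrative 3D Chromosome Reconstruction from Hi-C and FISH Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs three-dimensional chromosome models by jointly
    fitting Hi-C contact maps, imaging-derived (multiplexed FISH) mean
    pairwise distances between topologically associating domains (TADs),
    and a polymer conformational energy.  A divide-and-conquer strategy
    first embeds a TAD-level backbone by minimising a stochastic-neighbour
    Kullback-Leibler objective with FISH distance restraints, then models
    each TAD at bin resolution under a radius-of-gyration constraint, and
    finally assembles the TAD models into the backbone by rigid-body
    rotation and reflection.  Includes parameter selection by grid search
    on a volume-matching score, model-quality metrics (relative error
    against FISH, A/B compartment calling, asphericity, TAD density,
    Hi-C/FISH consistency), and a synthetic ground-truth generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    GenomeInfoDb,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
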