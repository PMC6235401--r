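Package: ycontent
Title: Phylogenetic Analysis of Y-Chromosome Gene-Content Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to reconstruct the evolutionary history of Y-linked gene
    content from male/female PCR amplification surveys placed on a phylogeny.
    Provides Dollo/Fitch/Sankoff parsimony reconstruction of per-gene linkage
    states, counting and classification of independent gene-movement events
    (single-gene transfers, genomic losses, grouped transfers, whole-Y
    incorporations), exact Poisson rate estimation with Garwood confidence
    intervals, an exact conditional test for the ratio of two Poisson means,
    a two-tailed Fisher exact test for gene "re-acquisition" tables, and a
    forward simulator of the duplicated-Y model (an incorporated Y leaves
    redundant Y and autosomal/X copies that resolve at random along
    lineages), which doubles as the synthetic-data generator used for
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    knitr,
    phangorn,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
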