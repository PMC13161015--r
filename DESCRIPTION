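Package: flocknet
Title: Trait Predictors of Species Nuclearity in Mixed-Species Flock
    Co-Occurrence Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking bird phenotypes to their structural role
    ("nuclearity") in mixed-species flock co-occurrence networks. Reads and
    filters per-locality flock-by-species occurrence matrices, computes
    flocking propensity and species-level network metrics (connectivity,
    strength, weighted closeness), standardizes observed metrics against
    fixed-row/fixed-column (curveball) null models as z-scores, assembles
    phylogenetically size-corrected trait predictors (beak-shape PCA,
    residual eye size, residual song frequency, plumage color classes),
    and fits phylogenetic comparative models: Pagel's lambda by maximum
    likelihood, PGLS, and a Bayesian phylogenetic linear mixed model whose
    posterior is pooled across a sample of trees. A synthetic-data module
    generates complete studies (tree, traits, flocks) with known ground
    truth so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    nlme,
    phytools,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
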