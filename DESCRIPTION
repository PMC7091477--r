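Package: polyquant
Title: Quantitative Analysis of Fibrillar Alpha-Synuclein Polymorph Behaviour on Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for the quantitative readouts used to
    characterise how fibrillar alpha-synuclein polymorphs bind, cluster,
    diffuse and perturb activity on cultured neurons. Provides density-based
    (DBSCAN) cluster analysis of single-molecule localization microscopy
    tables with blink correction and Gaussian rendering; a variational-Bayes
    hidden Markov model that infers one to three Brownian diffusive states
    from single-particle trajectories with evidence-based model selection;
    a-trous wavelet segmentation of fluorescent puncta with colocalization
    and surface-versus-internalized (endocytosis) metrics; multielectrode
    array spike detection and network firing-rate statistics; and synthetic
    generators for all four data modalities with known ground truth, so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
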