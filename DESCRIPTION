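Package: subseg
Title: Atlas-Guided Supervised Segmentation of Subcortical Brain Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic, atlas-guided training and supervised voxel
    classification of four subcortical brain structures (caudate, thalamus,
    pallidum, putamen) together with the three major intracranial tissues
    (gray matter, white matter, cerebrospinal fluid) from coregistered
    multispectral magnetic resonance volumes. Training voxels are selected on
    the target subject itself from thresholded, layered probabilistic atlases
    and fed to either a k-nearest-neighbour classifier on combined spatial and
    intensity features, or a principal-component discriminant-analysis
    classifier (PCA transform, per-class nonparametric density estimates,
    Bayes rule). Includes a seeded multispectral digital phantom generator
    with ground-truth labels and deliberately degraded atlases, and evaluation
    utilities for per-class volumes, scan-rescan percent volume differences,
    and Dice/Jaccard overlap indices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    stats,
    utils,
    withr,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
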