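Package: finesgs
Title: Fine-Scale Spatial Genetic Structure in Continuous Plant Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation and testing of fine-scale spatial genetic structure
    (SGS) from georeferenced codominant genotypes. Implements Loiselle/Nason
    pairwise kinship coefficients for diploid microsatellite and haploid
    plastid markers, kinship-distance distograms with permutation envelopes,
    the Sp statistic with jackknife-over-loci standard errors, Rosenberg
    bearing correlograms for directional (anisotropic) SGS, spatial principal
    component analysis of allele frequencies with global/local permutation
    tests, per-locus diversity summaries with Monte-Carlo Hardy-Weinberg
    tests, permutation-tested Weir-Cockerham F_ST and chord-distance AMOVA
    between cohorts, and spatially lagged simultaneous autoregressive models
    of genetic scores on environmental predictors with AIC-based multimodel
    averaging. A forward-in-time simulator of a facultative-biennial plant
    population with limited seed dispersal, short-distance pollen flow,
    inter-annual migrants, directional anisotropy and environment-coupled
    establishment provides ground-truthed inputs for validating every
    estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
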