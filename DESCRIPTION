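Package: dioecia
Title: Spatial Population Genetics of Dioecious Tree Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for mapped, sexed and genotyped dioecious
    tree populations inside a rectangular plot: sex-ratio G-tests and
    size-structure comparisons, per-cohort genetic diversity with bootstrap
    confidence intervals, fine-scale spatial genetic structure (Loiselle
    kinship autocorrelograms, kinship-distance regression and the Sp
    statistic with permutation envelopes), bivariate Ripley's K12/L12 with
    isotropic edge correction and random-labeling envelopes, likelihood
    parentage assignment with a genotyping-error model and exclusion
    probabilities, and effective versus realized pollen and seed dispersal
    kernels as a probe for distance-dependent (Janzen-Connell) recruitment.
    Includes a spatially explicit forward simulator of a dioecious
    population with known pedigree for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
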