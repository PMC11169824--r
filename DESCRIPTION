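Package: phenogs
Title: Phenomic and Genomic Prediction for Wheat Breeding with High-Throughput Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for UAV-assisted winter-wheat
    breeding trials. Generates synthetic breeding-trial datasets (SNP
    genotypes, replicated and augmented field designs, multitemporal 5-band
    canopy reflectance) with known ground truth; computes a 20-index
    vegetation-index catalog from plot-level reflectance; estimates per-line
    BLUEs and broad-sense heritability by profile REML; fits single-trait and
    multi-trait GBLUP models by Gibbs sampling with a genomic relationship
    matrix, including HTP-trait covariates; runs the ST-CV1 and MT-CV2
    cross-validation schemes; and trains a feedforward deep neural network
    for phenomic prediction of grain yield, test weight, and grain protein
    from multitemporal vegetation indices.
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
    vcfR
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
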