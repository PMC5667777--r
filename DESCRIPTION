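Package: ibdblocks
Title: Forward Simulation and Estimation of Identity-by-Descent Block Lengths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation of identity-by-descent (IBD) blocks in
    a finite, panmictic, monoecious diploid population without selfing,
    undergoing drift only. Chromosomes are modelled as continuous founder-origin
    mosaics on [0, l] Morgan; meiosis follows the Haldane no-interference model
    (Poisson crossover counts, uniform positions). The package extracts relaxed
    and strict IBD blocks between homologous chromosome pairs, classifies
    junctions as external or internal, and implements three mean block-length
    measures (across-replicate, population-wise and individual-wise) together
    with the junction-theory predictions of the expected block length,
    including the finite-chromosome tip correction. A compiled engine makes
    replicate-scale experiments (thousands of population trajectories)
    practical on a desktop machine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'cli.R'
    'estimators.R'
    'experiment.R'
    'genome.R'
    'ibd.R'
    'ibdblocks-package.R'
    'population.R'
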