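Package: cortexsim
Title: Desk-Scale Simulation and Analysis of Cortical Circuit Physiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing layered spiking cortical
    network models at desk scale. Implements a seeded surrogate network of
    leaky integrate-and-fire neurons with stochastic multivesicular
    Tsodyks-Markram synapses, Ornstein-Uhlenbeck somatic conductance
    injection compensating for unmodeled extrinsic input, and an iterative
    population-wise firing-rate calibration algorithm. Includes in silico
    experimentation utilities (thalamic stimulus pipelines, optogenetic
    light-attenuation models, pathway lesions), evoked-response validation
    metrics, contrast-tuning and optogenetic-modulation model fitting,
    mutual-information analysis of rate and synchrony codes, and
    structure-function analysis via directed-simplex node participation and
    meso-scale connectivity graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    minpack.lm,
    MASS,
    igraph,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
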