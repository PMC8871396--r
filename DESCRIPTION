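Package: wmnet
Title: Distributed Working Memory in a Large-Scale Primate Cortical Network Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and analysis toolkit for an anatomically constrained
    multi-area model of distributed working memory in the macaque neocortex.
    Each cortical area is a reduced three-population (two selective excitatory
    pools, one inhibitory pool) firing-rate circuit placed on a macroscopic
    gradient of recurrent excitation derived from dendritic spine counts;
    areas are coupled through tract-tracing connectivity (FLN) with
    feedforward/feedback asymmetry (SLN) and a counterstream inhibitory bias.
    Provides local-circuit bifurcation analysis, hierarchy estimation from
    SLN by logistic regression, synthetic connectome generation, working
    memory trial protocols (cue/delay, distractors, silencing, targeted
    shutdown, gating), a numerical attractor census with lesion survival
    analysis, and a simplified fully connected excitatory-node model with a
    first-order mean-field solution.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
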