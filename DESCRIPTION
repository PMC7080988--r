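Package: endmtbn
Title: Boolean Network Model of the Endothelial-to-Mesenchymal Transition
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A synchronous Boolean network model of the molecular regulatory
    network controlling endothelial cell activation and the
    endothelial-to-mesenchymal transition (EndMT), together with a complete
    analysis toolkit: exhaustive attractor enumeration of the 2^29 state
    space by microenvironment decomposition, marker-based classification of
    attractors into endothelial, mesenchymal, phalanx, stalk and tip cell
    classes, Monte Carlo trap-space (basin) estimation, derivation of the
    signed functional-interaction graph and its feedback circuits, in-silico
    knockout/overexpression scans, update-rule bit-flip robustness, state-noise
    sensitivity analysis, and perturbation-driven cell-fate transition mapping.
    General synchronous Boolean networks can be read from and written to the
    .bnet logical-model text format.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
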