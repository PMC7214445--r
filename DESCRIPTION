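Package: bdegnn
Title: Homolytic Bond Dissociation Enthalpies from 2D Structure with a
    Directed-Edge Message-Passing Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Enumerates the homolytic dissociations of every acyclic single
    bond of C/H/O/N organic molecules given as SMILES, predicts each bond's
    dissociation enthalpy (kcal/mol) with a message-passing graph neural
    network over categorical atom and bond classes (two directed edges per
    bond, residual blocks, batch normalization, per-bond-class mean
    baseline), and interprets predictions by nearest-neighbor search in the
    final-layer bond-embedding space. Also assembles enthalpy-based BDEs with
    statistical quality-control screens (Boltzmann conformer averaging,
    geometry connectivity, per-formula outlier rejection) and drives two
    downstream models: weakest-bond site-of-metabolism classification and a
    radical-fragment sooting-tendency regression. A synthetic molecule and
    label generator makes every component testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineOB,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
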