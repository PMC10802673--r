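Package: qcfnet
Title: Quartet Concordance Factors on Level-1 Phylogenetic Networks
Version: 0.1.0
Authors@R: person("qcfnet", "maintainers", email = "qcfnet@example.org",
    role = c("aut", "cre"))
Description: Exact computation of quartet concordance factors (CFs) under the
    network multispecies coalescent (NMSC) on binary level-1 phylogenetic
    networks, together with the algebraic and semialgebraic statistics that
    detect 2-, 3- and 4-cycle features from CF tables, closed-form recovery of
    identifiable numerical parameters (edge lengths in coalescent units and
    inheritance probabilities), a network-wide identifiability audit, and a
    Monte-Carlo NMSC gene-tree simulator for cross-validation. Networks are
    read and written in extended Newick; CF tables in a simple CSV format.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
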