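Package: rbnet
Title: Rule-Based Modeling and Network-Free Simulation of Signaling Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Specify combinatorially complex biochemical signaling models as
    molecule-type graphs plus reaction rules in a BNGL-style plain-text
    dialect, and simulate them with two complementary stochastic engines: a
    particle-based network-free algorithm whose per-event cost is independent
    of the size of the implied reaction network, and a population-based
    Gillespie algorithm with lazy (on-the-fly) reaction-network generation.
    Also provides exact enumeration of local docking-site states and
    monomer/dimer state-space counts, sampling of physically constrained
    parameter ensembles (log-uniform class ranges with detailed-balance
    enforcement on binding cycles), max-normalization and average-linkage
    Pearson clustering of site-specific phosphorylation time courses, and
    machine-readable contact-map extraction from rule sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
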