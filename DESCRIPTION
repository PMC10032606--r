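Package: idpscape
Title: Coarse-Grained Brownian Dynamics and Energy-Landscape Kinetics for
    Amyloidogenic Disordered Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for the monomer-to-dimer stage of
    amyloid aggregation in short intrinsically disordered peptides such as
    Abeta40 and Abeta42.  Implements a two-beads-per-residue self-organized
    polymer (SOP-IDP) energy function, overdamped Brownian dynamics with
    optional Rotne-Prager-Yamakawa hydrodynamic interactions, fibril-overlap
    order parameters for detecting assembly-competent (N*) excitations, DRID
    feature clustering, min-cut transition disconnectivity graphs with
    landscape roughness profiles, Markov-chain implied timescales,
    graph-transformation and empirical first-passage-time analysis, and
    dimerization simulations summarised as hidden-Markov-model transition
    networks.  Includes synthetic fixture generators (toy fibril references,
    Markov emitters with known kinetics, self-avoiding random-coil ensembles)
    so the full pipeline is testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    seqinr,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
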