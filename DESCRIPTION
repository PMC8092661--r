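Package: nrpiturn
Title: Pi-Turn Signature Analysis of Nuclear Receptor Ligand-Binding Domains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects and traces the pi-turn (RxxxE) signature of nuclear
    receptor ligand-binding domains. Classifies helix conformations (alpha,
    3-10, pi) from backbone hydrogen-bond patterns using a Kabsch-Sander
    electrostatic energy model, scans multiple sequence alignments for the
    RxxxE motif and its degraded variants, audits class I/II dimerization
    markers in the Brelivet numbering, maps generic alignment positions to
    native residue numbers, enumerates and types dimer-interface contacts
    (hydrogen bonds, salt bridges, van der Waals, water-mediated), computes
    buried surface area by Shrake-Rupley sampling, and reconstructs the
    motif's evolutionary history on a phylogeny via symmetric-rate Markov
    models: pruning likelihoods, maximum-likelihood rates, marginal ancestral
    states, stochastic character mapping, and Dollo/Fitch parsimony loss
    counts. Ships synthetic generators (ideal helices with planted pi-bulges,
    toy dimers, planted-motif alignments, simulated character histories) so
    the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
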