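Package: covrapid
Title: Covalent Peptide Discovery Analytics: Inhibition Kinetics, SPR, and
    mRNA-Display Selection Deconvolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for covalent macrocyclic peptide discovery
    campaigns against enzyme targets such as peptidyl arginine deiminase 4
    (PADI4). Implements time-dependent potency analysis for covalent
    inhibitors (four-parameter logistic IC50 fits per quench time and the
    implicit Krippendorff IC50(t) model yielding K_I and k_inact), surface
    plasmon resonance two-state reaction-model simulation and fitting with
    an irreversible second step, and deconvolution of selection
    next-generation sequencing reads into cyclic peptides under a
    reprogrammed genetic code (chloroacetyl-D-tyrosine initiator, internal
    Met codons reassigned to an electrophilic warhead), with per-round
    enrichment, warhead-content and sequence-family statistics. Seeded
    synthetic-data generators emulate the plate assays, sensorgrams and
    NNK-degenerate selection libraries so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
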