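Package: phosphoTBM
Title: Phospho-Regulated Tankyrase-Binding Motif Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying phosphorylation-dependent recruitment of
    effector proteins to tankyrase ankyrin repeat clusters (ARCs).
    Implements PSSM-based scanning of proteomes for tankyrase-binding
    motif (TBM) octapeptides with a tankyrase targeting score, cross-
    referencing of motif hits against phosphosite tables with position-8
    phospho-arm classification, hypergeometric term over-representation
    analysis, kinase-preference scoring of phosphoacceptor windows,
    fitting of fluorescence-polarization titrations with a one-site
    total-binding model to derive dissociation constants and affinity
    fold changes, rigid-body superposition and contact analysis of
    ARC-peptide structures, per-residue conservation mapping, and a
    seeded synthetic-data generator that plants motifs, phospho-events,
    term enrichment, titrations and toy structures with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
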