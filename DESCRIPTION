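Package: ppiddg
Title: Predicting Changes in Protein-Protein Binding Affinity upon
    Missense Mutation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Structure-based prediction of the change in protein-protein
    binding free energy caused by single-point missense mutations.
    Implements graph-based structural signatures of the wild-type residue
    environment (pharmacophore-typed cutoff scanning), typed non-covalent
    contact networks of binding interfaces, residue environment
    descriptors, evolutionary (PSSM) and contact-potential scores, elastic
    network model fluctuations, SKEMPI-style dataset curation with
    antisymmetric reverse-mutation augmentation, tree-ensemble regression
    with alanine-scanning and saturation-mutagenesis modes, and the
    associated validation statistics (redundancy-aware cross-validation
    splits, correlation comparison tests, hotspot classification).
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    ranger,
    jsonlite,
    seqinr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
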