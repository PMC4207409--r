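Package: hlamod
Title: Homology Modeling of HLA Peptide-Binding Grooves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated homology modeling of class I and class II human
    leukocyte antigen (HLA) molecules from a query allele sequence. Builds
    and queries a local database of HLA crystal structures, selects
    templates by binding-site sequence identity, constructs models of the
    antigenic peptide-binding groove by segment-matching backbone
    inheritance with rotamer-based side-chain placement and tethered
    soft-sphere relaxation, threads antigenic peptides onto the conserved
    bound-peptide backbone over all registrations with an interface score,
    and validates models by Kabsch-superposition RMSD and leave-one-out
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
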