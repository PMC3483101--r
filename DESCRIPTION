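Package: rogval
Title: Residue-Based Red/Orange/Green Validation of NMR Structure Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Residue-oriented quality assessment of multi-model NMR structure
    ensembles. Computes per-residue dihedral statistics including the D1/D2
    virtual dihedrals, selects well-defined residue ranges by phi/psi circular
    variance, superposes ensembles and reports RMSD to the mean coordinates,
    analyses distance and dihedral restraint violations (r^-6 effective
    distances, duplicate detection, sequence-range classes, simplified NOE
    completeness), checks chemical shifts against reference statistics and
    peak-assignment consistency, detects salt bridges and disulfide bonds,
    and aggregates everything into a three-level red/orange/green (ROG)
    score per residue, chain and molecule with machine-readable and static
    HTML reports. Includes a deterministic synthetic-data generator so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
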