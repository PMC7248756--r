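Package: oligorot
Title: Quaternary-Structure Rotation and Fluctuation Analysis for Oligomeric Repressors
Version: 0.1.0
Authors@R:
    person("Oligorot", "Developers", email = "oligorot@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for trajectories and crystal structures of
    hexameric (trimer-of-trimers) proteins such as the bacterial arginine
    repressor ArgR. Quantifies the signed trimer-trimer rotation angle from
    subunit centers of mass, scores salt-bridge and hydrogen-bond occupancies
    by heavy-atom distance criteria, computes RMSD/RMSF profiles and their
    crystallographic B-factor conversion, estimates quasi-harmonic and
    Schlitter configurational entropies from mass-weighted covariance matrices
    of atomic fluctuations, performs PCA of global motions, classifies ArgR
    family sequences by their group-defining linker/binding-site motifs, and
    generates ground-truthed synthetic rigid-body hexamer trajectories for
    validation of all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
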