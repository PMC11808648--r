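Package: nanotraj
Title: Contact, Geometry and Energetics Analysis of Protein-Nanodisc
    Binding Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics trajectories of
    peripheral membrane proteins binding lipid nanodiscs. Provides
    moiety-resolved protein-lipid contact occupancy maps with a hard
    distance cutoff, membrane tilt angles constructed from scaffold
    anchor residues, Shrake-Rupley solvent-accessible surface area and
    bound-versus-unbound delta-SASA, Kabsch superposition with backbone
    RMSD/RMSF, radial distribution functions with the potential of mean
    force transform, and a cutoff Coulomb plus Lennard-Jones interaction
    energy surrogate with lowest-energy frame extraction. Includes
    readers and writers for multi-model PDB, GRO and XYZ, an atom
    selection mini-language, a CHARMM36-dialect lipid moiety
    classification table for DOPC/DOPS bilayers, and a deterministic
    synthetic nanodisc-binding trajectory generator with planted ground
    truth for validating every analysis stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
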