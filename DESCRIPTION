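Package: sbmr
Title: Structure-Based (Go-Type) Models: Topology Generation, Langevin
    Dynamics and Folding Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generates simulation-ready structure-based ("Go-type") model
    topologies from PDB structures and declarative XML forcefield templates,
    in a GROMACS-dialect format. Covalent connectivity is compiled from
    per-residue template definitions, angles and dihedrals are enumerated from
    the bond graph, and native geometry parameterizes every
    structure-determined term (bond lengths, angles, dihedral phases, contact
    distances). Includes native contact map generation (distance cutoff with
    an optional line-of-sight occlusion filter), automatic coarse-graining to
    one bead per residue (C-alpha models), a reduced-units Langevin dynamics
    engine for the generated Hamiltonians, and analysis tools for folding
    thermodynamics: fraction of native contacts Q, free-energy profiles F(Q),
    specific heat curves and folding temperatures, contact-formation maps,
    and principal component analysis of domain centre-of-mass motions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    xml2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
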