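Package: macrocycler
Title: Target-Templated Design of Heterochiral Macrocyclic Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A structure-based toolkit for the de novo design of head-to-tail
    cyclized peptides that mix L- and D-amino acids, built around a fixed
    hotspot residue docked on a target protein. Provides internal-coordinate
    peptide geometry, PDB input/output with D-residue support, chirality-aware
    Ramachandran bin sampling, an analytic triaxial kinematic closure solver
    for macrocyclic backbones, a simplified decomposable energy function with
    hydrogen-bond detection, interface metrics (Shrake-Rupley solvent
    accessible surface area, buried interface area, Lawrence-Colman shape
    complementarity), Monte-Carlo sequence/rotamer design under the
    phi-sign chirality rule, and conformational energy-landscape funnel
    analysis for assessing structural pre-organization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
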