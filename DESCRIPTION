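Package: rdcfold
Title: Protein Backbone Structure Determination from Residual Dipolar Couplings
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Torsion-space assembly of protein backbones from residual
    dipolar couplings (RDCs). Candidate phi/psi pairs for every junction of
    adjoining peptide planes are enumerated, Ramachandran-filtered and ranked
    by fitness to the RDC data through best-fit Saupe order tensors; a beam
    search then elongates the chain peptide plane by peptide plane, pruning
    the fragment pool with an adaptive percentage-of-best-score (dynamic
    decimation) rule. Supports NMR Exchange Format (NEF) restraint lists with
    arbitrary backbone atom-pair RDCs as well as the legacy six-column
    per-residue format, simulation of RDC datasets from known structures
    under specified order tensors, and data-driven dihedral restraints mined
    from a local fragment library with a rolling sequence window.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, bio3d, pracma, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
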