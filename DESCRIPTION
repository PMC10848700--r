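Package: densiwit
Title: Topological Fidelity Witnesses for Quantum-Computed Electron Densities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constructs molecular electron densities from Gaussian-basis
    orbitals and (possibly noisy) one-particle reduced density matrices,
    applies symmetrization and trace-rescaling error mitigation to the
    density matrix, performs QTAIM topological analysis (critical points,
    Hessian signatures, Bader basins, atomic partial charges, non-nuclear
    attractors), and compares topological feature sets against a trusted
    reference ("witness") density. Reads and writes XYZ, Molden and
    Gaussian cube formats, and ships noise-free active-space density
    matrices for small benchmark molecules.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
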