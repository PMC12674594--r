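Package: neodh
Title: Multicomponent Double-Hybrid Density Functional Theory for Quantum Protons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nuclear-electronic orbital (NEO) Kohn-Sham theory in which selected
    protons are treated quantum mechanically alongside the electrons, with
    electron-proton correlation described by a tunable admixture of the epc-17.2
    local-density functional and a second-order Moller-Plesset (MP2) perturbative
    term evaluated on the converged multicomponent Kohn-Sham orbitals. Provides a
    self-contained Gaussian integral engine (McMurchie-Davidson), restricted
    Kohn-Sham and coupled electron-proton SCF solvers with DIIS acceleration,
    density-fitted and conventional MP2 (opposite-/same-spin resolved and
    electron-proton), double-hybrid functional assemblies (B2PLYP, DSD-PBEP86,
    PBEQIDH and their NEO counterparts), proton-affinity thermochemistry with the
    embedded PA21 and test benchmark tables, Bayesian optimization of the
    correlation admixture (Matern-5/2 Gaussian process, expected improvement),
    and voxel-based electronic density-difference analysis along bond axes.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    lhs,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
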