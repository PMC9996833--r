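Package: pnof
Title: Electron-Pairing Natural Orbital Functionals (PNOF5, PNOF7s, PNOF7, GNOF)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Natural orbital functional (NOF) theory for molecular electronic
    structure with electron-pairing constraints. Implements the PNOF5, PNOF7s,
    PNOF7 and GNOF energy expressions over natural orbitals and their occupation
    numbers, the orbital-space partition into single-electron and paired-electron
    subspaces, constrained occupation-number optimization (exact subspace sum
    rules via an interior parametrization) alternated with natural-orbital
    rotations, and solution diagnostics (M diagnostic for static versus dynamic
    correlation, 1RDM trace checks, adiabatic spin gaps, molden/cube orbital
    export). Ships a compact McMurchie-Davidson Gaussian integral engine
    (s/p/d shells, spherical harmonics, optional Cholesky-factorized electron
    repulsion integrals), a determinant full-configuration-interaction oracle,
    and desk-scale model systems (H, H2, H4 chains, LiH, H2O) so everything is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
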