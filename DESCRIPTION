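Package: qcdmrg
Title: Spin-Adapted Density Matrix Renormalization Group for Active-Space
    Hamiltonians
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ground-state solver for active-space quantum-chemistry
    Hamiltonians based on the density matrix renormalization group (DMRG)
    over matrix product states, with particle-number and spin symmetry
    handling in two modes: Sz-resolved U(1) bookkeeping and SU(2)
    multiplet accounting with singlet embedding and total-spin targeting.
    Includes a Molpro-dialect FCIDUMP reader/writer, synthetic model
    Hamiltonian generators (Hubbard chains, randomized symmetric integral
    tables), a block-sparse symmetric tensor engine with exact
    floating-point-operation accounting, a Davidson two-site sweep
    optimizer, a full configuration interaction oracle for small active
    spaces, and an analysis layer for 1/D bond-dimension extrapolation of
    spin-state energies, spin gaps, and log-log cost-scaling fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
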