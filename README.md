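# qcdmrg

Spin-adapted density matrix renormalization group (DMRG) ground-state
solver for active-space quantum-chemistry Hamiltonians, in pure R, with
the standard analysis layer for bond-dimension studies: 1/D extrapolation
of spin-state energies, spin gaps, and log-log cost-scaling fits.

## Who this is for

Researchers and students who want a transparent, fully testable reference
implementation of quantum-chemistry DMRG at desk scale: every energy the
solver produces on its shipped fixtures can be checked against an exact
full configuration interaction (FCI) oracle that ships in the same
package. It is not a production code — no point-group symmetry, no
orbital reordering, no accelerator dispatch — but the algorithms are the
real ones.

## The model and the method

The solver treats the active-space Hamiltonian

    H = E_core + sum_pq h_pq sum_s a+_ps a_qs
        + 1/2 sum_pqrs (pq|rs) sum_st a+_ps a+_rt a_st a_qs

with `(pq|rs)` in chemists' notation, read from Molpro-dialect FCIDUMP
files or generated internally (Hubbard chains; randomized exactly
8-fold-symmetric integral tables). The wave function is a matrix product
state over N spinful orbitals (local dimension 4); optimization is
two-site DMRG with a preconditioned Davidson eigensolver, block-sparse
symmetric tensors, and exact floating-point-operation accounting. The
Hamiltonian is compressed into a matrix product operator with
complementary-operator-scale bond dimension by exact rank reduction of a
symbolic term automaton.

Two symmetry modes share one interface:

* `u1` — particle number and Sz conservation; bond caps count states;
* `su2` — total-spin targeting via singlet embedding (a spin-S ancilla
  closes the state to a global singlet) plus an `S^2` penalty, with bond
  caps counting SU(2) multiplets, whole-multiplet truncation, and
  per-bond multiplet spectra whose U(1) dimension
  `sum multiplicity * (2S+1)` reconciles the two accountings.

## A worked example

```r
library(qcdmrg)

# half-filled 6-site Hubbard chain, U/t = 4, singlet ground state
tb <- hubbard_chain(6, t = 1, u = 4)

res <- run_dmrg(tb, target = c(6, 0),
                schedule = sweep_schedule(d_max = c(16, 64), n_sweeps = 2,
                                          max_sweeps = 12, energy_tol = 1e-9),
                seed = 1, mode = "su2")
res
#> <dmrg_result> E = -3.0925653195 Ha (su2 mode, target n=6, 2S=0), converged
#>   sweeps: 4, final D_U(1) = 64, total flops = 12,344,708

fci_lowest_with_spin(tb, two_s = 0)$energy
#> [1] -3.092565

res$multiplet_spectra[[3]]          # mid-bond retained basis, as multiplets
#>   two_s multiplicity
#> 1     0           14
#> 2     1           14
#> 3     2            6
#> 4     3            1
```

The run converges to the exact singlet energy (-3.0925653195 Hartree,
equal to the FCI oracle to ten digits); the mid-bond basis decomposes
into 35 SU(2) multiplets carrying 14 + 14x3 + 6x5 + 1x7 = 64 U(1)
states, the full mid-bond space of a 6-site chain. A bond-dimension
study and extrapolation:

```r
scan <- scan_bond_dimension(tb, c(6, 8, 12, 16, 24), target = c(6, 0),
                            mode = "su2", seed = 3, sweeps_per_d = 6,
                            measure_iters = 0)
fit <- extrapolate_vs_inverse_d(scan$realized_D, scan$energy, order = 2)
fit$extrapolated
#> [1] -3.092247
```

i.e. the D -> infinity intercept (-3.092247) lands within 0.32 mHartree
of the exact energy, six times closer than the smallest-cap run
(-3.090534, 2.0 mHartree off).

## Command line

A thin wrapper is installed at `inst/cli/qcdmrg` (subcommands `run`,
`scan-d`, `extrapolate`, `oracle`, `gen`); it writes reproducible run
bundles (sweep CSV, JSON summary, resolved YAML config, checkpoint).

```sh
Rscript inst/cli/qcdmrg gen --kind hubbard --n 2 --u 4 --out dimer.fcidump
Rscript inst/cli/qcdmrg oracle --fcidump dimer.fcidump
# FCI ground state (n=2, 2Sz=0): E = -0.8284271247 Ha, <S^2> = 0.000000
```

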